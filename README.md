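# ventstrain

Simulation of passive mechanical ventilation in a mechanically heterogeneous,
multi-compartment lung, with per-compartment energetics: intracycle elastic
power, delivered elastic energy, strain and strain rate.

## The problem and who this is for

Ventilator-induced lung injury (VILI) is driven by the repeated delivery of
mechanical energy to lung tissue and the strain it produces. Whole-lung
("single-compartment") analyses show that clinician-selected inspiratory flow
profiles differ sharply in *when* and *how fast* energy is delivered within a
breath. In the acutely injured lung, however, mechanics are regionally
heterogeneous, and the interesting question is how a globally applied flow or
pressure profile *distributes* power and strain among regions with different
resistance and compliance. `ventstrain` is for researchers in respiratory
physiology and ventilator mechanics who want a transparent, fully scripted
model of that distribution.

## The model

The lung is an electrical-analog circuit: a rigid, non-storing airway tree
with shared proximal resistances `R0..R3` (cmH2O·s/l) feeding five elastic
compartments `A..E`, each reached through its own terminal resistance `R_i`
and characterised by a linear compliance `C_i` (l/cmH2O) and a resting
(unstressed) volume `V_rest,i` (l). With `v_i` the absolute elastic volume of
compartment *i* (alveolar pressure `v_i / C_i`), Kirchhoff pressure/flow
balances at the internal nodes reduce the network to a linear ODE

```
dv/dt = A v + b u(t)
```

where `u(t)` is the airway boundary: a prescribed inspiratory flow `Q_aw(t)`
(constant CF, decelerating-triangular DF, half-sinusoidal SF) or a prescribed
constant pressure `P_set` (CP), and PEEP at the airway opening during passive
expiration. The breath-to-breath cycle map is affine, so the periodic steady
state — including each compartment's end-expiratory pressure
`P_ex = PEEP + auto-PEEP` — is identified exactly and verified by a
confirmation cycle.

Per compartment, on the inspiration grid:

- intracycle elastic power `ICP_elastic(t) = Q(t) (V(t)/C + P_ex)`,
- delivered elastic energy `A(t) = ∫₀ᵗ ICP_elastic ds`,
- strain `strain(t) = 1 + (V(t) + C·P_ex)/V_rest`
  (equivalently `1 + sqrt(2CA(t) + C²P_ex²)/V_rest`),
- strain rate `Q(t)/V_rest` (the literal energy-form variant, smaller by the
  factor `C`, is kept alongside), and
- maximal strain `S_max = max_t strain(t)`, which reduces to
  `1 + (V_T,comp + C·P_ex)/V_rest` when the compartment peaks at
  end-inspiration.

Scripted experiments sweep PEEP (0–12.75 cmH2O), tidal volume × peak flow,
and resting volume (0.2–1.2 l, uniform or per-compartment) across the four
modes at matched tidal volume.

## Worked example

```r
library(ventstrain)
sc   <- baseline_scenario()   # 5 compartments, PEEP 2, ti 1 s, ttot 3 s, CF 1.7 l/s
traj <- find_periodic_steady_state(sc$network, sc$ventilator)
traj
#> <cycle_trajectory> mode=CF  V_T=1.7000 l  PEEP=2 cmH2O
#>   P_ex (total PEEP, cmH2O): A=2.169  B=3.275  C=3.022  D=2.703  E=2.560
#>   grid: 3001 samples, dt=0.001 s, steady-state residual 1.6e-12 l
compute_energetics(traj)
#> <energetics_trace> mode=CF, strain rate: consistent form
#>  compartment  S_max t_peak  v_peak V_T_comp   P_ex    A_ti max_strain_rate
#>            A 2.0841  1.000 0.91055  0.91055 2.1688 7.15673         1.54235
#>            B 1.4526  1.020 0.25610  0.25577 3.2753 1.38290         0.37523
#>            C 1.3993  1.027 0.24820  0.24759 3.0222 1.36126         0.35084
#>            D 1.1832  1.000 0.12918  0.12918 2.7025 0.76629         0.15710
#>            E 1.2081  1.000 0.15691  0.15691 2.5596 1.01712         0.16845
```

Reading this: the 1.7 l breath splits very unevenly — the compliant, fast
compartment A takes 0.91 l and reaches a maximal strain of 2.08 (more than
doubling its resting volume), while the stiff, slow compartment D takes
0.13 l (S_max 1.18). The slow compartments B and C trap gas (total PEEP 3.3
and 3.0 cmH2O against an applied PEEP of 2) and keep filling briefly *after*
end-inspiration (`t_peak` 1.02, 1.03 s) as gas redistributes from faster
neighbours (pendelluft). `A_ti` is the elastic energy (cmH2O·l) each
compartment receives per breath.

Sweeps and mode comparisons:

```r
ps <- peep_sweep(sc$network, sc$ventilator)                # Smax vs PEEP, 4 modes
vs <- vrest_sweep(sc$network, sc$ventilator)               # Smax vs Vrest, CF/CP
mc <- mode_comparison(sc$network, sc$ventilator)           # all modes at VT = 1.7 l
h  <- heterogeneous_vrest(sc$network, sc$ventilator)       # per-compartment Vrest
```

A thin command-line front end is installed with the package:

```sh
VS=$(Rscript -e 'cat(system.file("exec","ventstrain",package="ventstrain"))')
CFG=$(Rscript -e 'cat(system.file("extdata","baseline.yaml",package="ventstrain"))')
Rscript $VS simulate --config $CFG --out out/          # trajectory + energetics + summary
Rscript $VS sweep    --config $CFG --experiment peep --out out/
Rscript $VS validate --config $CFG
```

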