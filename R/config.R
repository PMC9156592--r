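#' Read a scenario configuration file
#'
#' Scenario files are YAML with two top-level blocks: `network`
#' (`shared_resistances`, `topology`, `compartments`) and `ventilator`
#' (`mode`, `peep`, `ti`, `ttot` and exactly one amplitude key among `q_aw`,
#' `q_max`, `p_set`, `target_vt`). All quantities are plain numbers in
#' cmH2O / l / s. Files written by [write_scenario()] round-trip numerics
#' bit-exactly.
#'
#' @param path path to a YAML scenario file.
#' @return list with elements `network` and `ventilator`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_scenario(baseline_scenario(), f)
#' sc <- read_scenario(f)
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$network) || is.null(raw$ventilator))
    stop("config must have top-level 'network' and 'ventilator' blocks")
  nb <- raw$network
  sr <- unlist(nb$shared_resistances)
  topo <- do.call(rbind, lapply(nb$topology, function(e) {
    data.frame(from = e$from, to = e$to,
               r = if (is.null(e$r)) NA_character_ else e$r,
               stringsAsFactors = FALSE)
  }))
  comps <- do.call(rbind, lapply(nb$compartments, function(cc) {
    data.frame(label = cc$label, R = cc$r, C = cc$c, V_rest = cc$v_rest,
               stringsAsFactors = FALSE)
  }))
  net <- lung_network(sr, topo, comps)
  vb <- raw$ventilator
  amp_keys <- intersect(names(vb), c("q_aw", "q_max", "p_set", "target_vt"))
  if (length(amp_keys) != 1L)
    stop("ventilator block must carry exactly one amplitude key ",
         "(q_aw | q_max | p_set | target_vt)")
  args <- list(mode = vb$mode, peep = vb$peep, ti = vb$ti, ttot = vb$ttot)
  args[[amp_keys]] <- vb[[amp_keys]]
  vent <- do.call(ventilator_settings, args)
  list(network = net, ventilator = vent)
}

scenario_as_list <- function(scenario) {
  net <- scenario$network
  vent <- scenario$ventilator
  topo <- lapply(seq_len(nrow(net$topology)), function(i) {
    e <- net$topology[i, ]
    out <- list(from = e$from, to = e$to)
    if (!is.na(e$r)) out$r <- e$r
    out
  })
  comps <- lapply(seq_len(nrow(net$compartments)), function(i) {
    cc <- net$compartments[i, ]
    list(label = cc$label, r = cc$R, c = cc$C, v_rest = cc$V_rest)
  })
  vb <- list(mode = vent$mode, peep = vent$peep, ti = vent$ti, ttot = vent$ttot)
  vb[[vent$amplitude_kind]] <- vent$amplitude
  list(network = list(shared_resistances = as.list(net$shared_resistances),
                      topology = topo, compartments = comps),
       ventilator = vb)
}

#' Write a scenario configuration file
#'
#' @param scenario list with `network` and `ventilator` (as returned by
#'   [baseline_scenario()] or [read_scenario()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  txt <- yaml::as.yaml(scenario_as_list(scenario), precision = 22)
  writeLines(txt, path)
  invisible(path)
}

#' Hash of a scenario
#'
#' MD5 of the canonical YAML serialisation; used for sweep provenance and the
#' run manifest so identical inputs are recognisably identical.
#'
#' @inheritParams write_scenario
#' @return character MD5 digest.
#' @export
scenario_hash <- function(scenario) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_scenario(scenario, f)
  unname(tools::md5sum(f))
}
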