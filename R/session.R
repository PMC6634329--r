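#' Process one block end to end
#'
#' Raw trace to labelled per-cycle F1 records: preprocessing
#' ([preprocess()]) followed by cycle extraction ([extract_cycles()]).
#'
#' @param trace raw [pupil_trace()].
#' @param tl reported [percept_timeline()].
#' @param sch [stimulus_schedule()].
#' @param k_sd,pad_ms,min_run_ms preprocessing parameters, see
#'   [preprocess()].
#' @return list with `cycles` (data.frame), `trace` (cleaned) and
#'   `report` ([cleaning_report()]).
#' @export
process_block <- function(trace, tl, sch, k_sd = 5, pad_ms = 50,
                          min_run_ms = 0) {
  pp <- preprocess(trace, k_sd = k_sd, pad_ms = pad_ms,
                   min_run_ms = min_run_ms)
  cycles <- extract_cycles(pp$trace, tl, sch)
  list(cycles = cycles, trace = pp$trace, report = pp$report)
}

#' Simulate and analyze a multi-subject synthetic study
#'
#' For each simulated subject and each requested phase-offset condition:
#' draw a rivalry block ([simulate_block()]), clean it ([preprocess()])
#' and extract labelled cycles ([extract_cycles()]). The result feeds
#' [decode_session()] directly. Per-subject block seeds are derived
#' deterministically from `seed`, so the whole study is reproducible from
#' one integer.
#'
#' @param n_subjects number of simulated observers (default 12).
#' @param conditions character vector of condition labels (subset of
#'   [CONDITION_LABELS] excluding `"static"`).
#' @param params a [simulation_params()].
#' @param cfg a [default_config()] (schedule + preprocessing settings).
#' @param seed integer master seed.
#' @return data.frame of cycle records with `subject` and `condition`
#'   columns prepended.
#' @export
run_synthetic_study <- function(n_subjects = 12,
                                conditions = c("mod180_naive",
                                               "mod90_naive",
                                               "mod0_control"),
                                params = simulation_params(),
                                cfg = default_config(),
                                seed = 1) {
  out <- list(); k <- 0
  for (s in seq_len(n_subjects)) {
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      sch <- block_schedule(cond, face_left = s %% 2 == 1, cfg)
      blk_seed <- (as.integer(seed) * 1009L + s * 131L + ci) %% 2147483647L
      blk <- simulate_block(params, sch, seed = blk_seed,
                            block_id = sprintf("s%02d_%s", s, cond))
      pb <- process_block(blk$trace, blk$reported, sch,
                          k_sd = cfg$preprocessing$k_sd,
                          pad_ms = cfg$preprocessing$pad_ms,
                          min_run_ms = cfg$preprocessing$min_run_ms)
      cy <- pb$cycles
      cy$subject <- sprintf("s%02d", s)
      cy$condition <- cond
      k <- k + 1
      out[[k]] <- cy
    }
  }
  do.call(rbind, out)
}
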