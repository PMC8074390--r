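# The scaled-down synthetic study: three fixed seeds of the full protocol
# (generate population -> NMF -> CAE -> predictors -> learned optimizers ->
# online adaptation). Built once and shared; only the metrics are kept.
study_runs <- function() {
  fixture("study_runs", function() {
    lapply(1:3, function(sd) {
      rep <- run_experiment(experiment_config(), seed = sd)
      out <- rep[c("tvaf", "angle", "event", "event_inter")]
      out$cycle_ms <- rep$model$config$cycle_period_mean * 1000
      rm(rep)
      gc(verbose = FALSE)
      out
    })
  })
}

# Mean absolute time-to-IC error among samples whose true label lies in
# [lo, hi] x nominal stride duration.
event_err_band <- function(ev, cycle_ms, lo, hi) {
  err <- abs(ev$predictions - ev$labels)
  sel <- ev$labels >= lo * cycle_ms & ev$labels <= hi * cycle_ms
  mean(err[sel])
}
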