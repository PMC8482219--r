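# The full-density camera sweep is shared by several acceptance checks;
# compute it once per test run, lazily.
.acc_cache <- new.env(parent = emptyenv())

acc_full_sweep <- function() {
  if (is.null(.acc_cache$sw)) {
    t0 <- Sys.time()
    .acc_cache$sw <- evaluate_sweep(scene(), methods = gaze_methods(),
                                    collect = "moments")
    .acc_cache$elapsed <- as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))
  }
  .acc_cache$sw
}
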