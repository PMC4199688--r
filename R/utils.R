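# Set a seed for the calling function's lifetime, restoring the caller's
# RNG state on exit so simulation helpers have no side effects.
seed_locally <- function(seed, env = parent.frame()) {
  withr::local_preserve_seed(.local_envir = env)
  set.seed(seed)
}
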