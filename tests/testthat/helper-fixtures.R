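# Shared fixtures. Models are cheap to build; heavier simulation products are
# memoised per test run.

human_lung <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_human_lung(70)
    m
  }
})

sheep_lung <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_sheep_lung(40)
    m
  }
})

# converged tightly so the slow venous CO2 store has fully settled
resting_ss <- local({
  s <- NULL
  function() {
    if (is.null(s))
      s <<- steady_state(build_human_lung(70), work = 0,
                         solver = list(ss_tol = 2e-4, max_breaths = 400))
    s
  }
})

# Table 3 as printed (volume % of total, height % from base), used to compute
# distribution oracles independently of the anatomy builder.
table3 <- function() read_anatomy_table("human_lung_segments.tsv")
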