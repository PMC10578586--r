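# Shared fixtures, computed once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_domain <- function() radial_domain()
default_wt <- function() genotype_params("wt")

# default single-genotype day-7 colony run, shared by several tests
day7_run <- function() fixture("day7", {
  dom <- default_domain()
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 2)))
  simulate_colony(st, list(default_wt()), dom, 168, dt = 0.1,
                  record_times = c(0, 24, 72, 168))
})

# default synthetic transcriptome plus the inference pipeline over it
default_tx <- function() fixture("tx", gen_transcriptome(synthesis_config(seed = 1)))

default_norm <- function() fixture("norm", {
  tx <- default_tx()
  normalize_log(tx$counts, size_factors(tx$counts))
})

default_activity <- function() fixture("act", {
  suppressMessages(regulator_activity(default_norm(),
                                      default_tx()$truth$regulons))
})

default_som <- function() fixture("som", {
  nm <- default_norm()
  z <- t(scale(t(nm)))
  z <- z[apply(nm, 1, stats::sd) > 0, ]
  train_som(z, grid = c(10, 10), epochs = 50, seed = 1)
})

# brute-force BH step-up, independent of stats::p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}
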