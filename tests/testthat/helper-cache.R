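# Heavy shared objects, computed once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

cached_report <- function() {
  cached("report", run_paper_reproduction(verbose = FALSE))
}

# small embedded conformer set reused across MIF tests
cached_confs <- function() {
  cached("confs", embed_3d_batch(
    c(methane = "C", ethylene_glycol = "OCCO", glycerol = "OCC(O)CO",
      hexane = "CCCCCC", benzene = "c1ccccc1", ethanol = "CCO"),
    seed = 11, ids = c("methane", "glycol", "glycerol", "hexane",
                       "benzene", "ethanol")))
}

random_rotation <- function(seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0,
                 sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Rx
}
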