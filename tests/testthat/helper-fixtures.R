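# Shared fixture builders for the test suite. Everything is generated in
# code under explicit seeds; no data files.

# random score vector in [0,1]^n, optionally bounded away from the edges
randomScores <- function(n, lo = 0, hi = 1) stats::runif(n, lo, hi)

# random softmax-like column matrix (C x K), columns summing to 1
randomScoreMatrix <- function(C, K, captureId = "capture1") {
  g <- matrix(stats::rexp(C * K), nrow = C)
  s <- sweep(g, 2L, colSums(g), "/")
  ViewScoreMatrix(s, captureId = captureId)
}

# randomized (x, measure) instances cycling over the given n and q grids
randomInstances <- function(nInstances, ns = c(1, 2, 4, 8),
                            qs = c(0.5, 1, 2, 5), lo = 0, hi = 1) {
  grid <- expand.grid(n = ns, q = qs)
  lapply(seq_len(nInstances), function(i) {
    g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
    list(x = randomScores(g$n, lo, hi), m = powerMeasure(g$q, g$n))
  })
}

# path of the installed CLI script
cliPath <- function() {
  p <- system.file("cli", "choquetfuse.R", package = "ChoquetFusion")
  stopifnot(nzchar(p))
  p
}

runCli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2(rscript, c(cliPath(), ...), stdout = TRUE, stderr = TRUE,
            env = libs))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
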