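# Shared desk-scale fixtures: micro model configurations and a small
# synthetic-volume spec so every test runs in seconds.

microSpec <- function(...) {
  synthSpec(nSlices = 6L, height = 16L, width = 16L,
            lesionRadiusRange = c(2, 3), lesionSlabRange = c(2L, 3L), ...)
}

microVitConfig <- function(...) {
  vitConfig("tiny", side = 16, patch = 8, embedDim = 16, depth = 2, heads = 2,
            ...)
}

tinyVitConfig <- function(...) vitConfig("tiny", ...)

microAggConfig <- function(kind = "transformer", nSlices = 6L, ...) {
  aggregatorConfig(kind, embedDim = 16, nSlices = nSlices, ...)
}

# a tiny, quickly separable dataset for micro training runs
microDataset <- function(n, seed) {
  casesToDataset(generateDataset(microSpec(), n, seed = seed))
}

randomFeatures <- function(n, d, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# independent nested traversal of a parameter list (oracle for countParams)
traverseCount <- function(p) {
  if (is.list(p)) sum(vapply(p, traverseCount, numeric(1))) else length(p)
}
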