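# Brute-force oracles for the gating rules, written directly from their
# verbal definitions and kept independent of the package implementation.

# ED: strictly larger area than every neighbour within `window` on both
# sides; only indices with a full window on each side are eligible.
oracleED <- function(areas, window = 3L) {
  n <- length(areas)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (i - window < 1L || i + window > n) next
    nb <- c(areas[(i - window):(i - 1L)], areas[(i + 1L):(i + window)])
    if (all(areas[i] > nb)) hits <- c(hits, i)
  }
  hits
}

# ES: smallest area strictly between each consecutive ED pair, earliest on
# ties.
oracleES <- function(areas, ed) {
  out <- integer(0)
  for (k in seq_len(length(ed) - 1L)) {
    inner <- (ed[k] + 1L):(ed[k + 1L] - 1L)
    out <- c(out, inner[which.min(areas[inner])])
  }
  out
}

# small deterministic phantoms shared across tests via lazy memoisation;
# "default" keeps all physiological defaults but fewer slices for speed
.testPhantomCache <- new.env(parent = emptyenv())
testPhantom <- function(key = "default", ...) {
  if (is.null(.testPhantomCache[[key]])) {
    .testPhantomCache[[key]] <- if (key == "default")
      generatePhantom(phantomParams(nSlices = 3L, seed = 1L))
    else generatePhantom(phantomParams(...))
  }
  .testPhantomCache[[key]]
}

# diaphragm ROI matching the default phantom layout (edge near row 64)
testRoi <- function() roiSpec(1L, c(56L, 74L), c(5L, 30L))
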