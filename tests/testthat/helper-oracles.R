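# Independent oracles used across tests.

# Set-arithmetic classifier for the relation between two integer ranges,
# written against explicit position sets rather than endpoint comparisons so
# it is independent of the implementation's arithmetic cascade.
allen_oracle <- function(s1, e1, s2, e2) {
  A <- s1:e1; B <- s2:e2
  if (setequal(A, B)) return("equals")
  if (max(A) < min(B)) {
    return(if (max(A) + 1L == min(B)) "meets" else "strictlyPrecedes")
  }
  if (min(A) > max(B)) {
    return(if (min(A) == max(B) + 1L) "metBy" else "precededBy")
  }
  if (all(B %in% A)) { # A strictly bigger, B inside
    shared <- (min(A) == min(B)) || (max(A) == max(B))
    return(if (shared) "contains" else "strictlyContains")
  }
  if (all(A %in% B)) {
    if (min(A) == min(B)) return("starts")
    if (max(A) == max(B)) return("finishes")
    return("during")
  }
  if (min(A) < min(B)) "overlaps" else "overlappedBy"
}

# the converse names expected under argument swap; `contains` folds two base
# relations whose converses are starts / finishes
allen_converse <- c(
  equals = "equals",
  strictlyPrecedes = "precededBy", precededBy = "strictlyPrecedes",
  meets = "metBy", metBy = "meets",
  overlaps = "overlappedBy", overlappedBy = "overlaps",
  strictlyContains = "during", during = "strictlyContains"
)

all_test_ranges <- function(lo = 1L, hi = 8L) {
  out <- list()
  for (s in lo:hi) for (e in s:hi) out[[length(out) + 1L]] <- c(s = s, e = e)
  out
}

with_no_warnings <- function(expr) suppressWarnings(expr)
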