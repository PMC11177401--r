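# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Stable 32-bit string hash (polynomial rolling hash).  Used to derive
# per-individual RNG sub-streams so that adding individuals to a simulation
# never perturbs the draws of existing ones.
stable_hash <- function(s, mod = 2147483647) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% mod
  as.integer(h)
}

# Positions covered by a (possibly wrap-around) interval on a circular
# genome, in genomic 5'->3' order along the plus strand.
unroll_span <- function(start, end, L, circular = TRUE) {
  if (start <= end) return(seq.int(start, end))
  if (!circular) stopf("start > end (%d > %d) on a non-circular genome", start, end)
  c(seq.int(start, L), seq.int(1L, end))
}

span_length <- function(start, end, L) {
  if (start <= end) end - start + 1L else L - start + 1L + end
}
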