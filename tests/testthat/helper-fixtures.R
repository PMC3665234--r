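# Shared test helpers: small fingerprint and library builders.

# fingerprint with the given 1-based bit positions set
make_fp <- function(positions, n = 16L) {
  bits <- integer(n)
  bits[positions] <- 1L
  fingerprint(bits)
}

rand_bits <- function(n, density = 0.1) {
  as.integer(stats::runif(n) < density)
}

# tiny hand-assembled drug library on raw bit vectors
toy_library <- function() {
  drugs <- data.frame(
    drug_id = c("DB1", "DB2", "DB3"),
    name = c("alpha", "beta", "gamma"),
    stringsAsFactors = FALSE)
  drugs$atc_codes <- list(c("A01AA01"), c("A01AB02"), c("B01AA03"))
  drugs$targets <- list(c("OPRK1", "DRD2"), c("DRD2", "HTR1A"), c("ACE"))
  fp <- rbind(
    DB1 = c(1, 1, 1, 1, 0, 0, 0, 0),
    DB2 = c(1, 1, 0, 0, 1, 1, 0, 0),
    DB3 = c(0, 0, 0, 0, 0, 0, 1, 1))
  drug_library(drugs, fp)
}

# brute-force Tanimoto screen used as an independent oracle
brute_screen <- function(Q, lib, threshold) {
  hits <- list()
  for (i in seq_len(nrow(Q))) {
    for (j in seq_len(nrow(lib$fp))) {
      s <- tanimoto(fingerprint(Q[i, ]), fingerprint(lib$fp[j, ]))
      if (s >= threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          compound_id = rownames(Q)[i],
          drug_id = lib$drugs$drug_id[j],
          score = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(compound_id = character(), drug_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$compound_id, -out$score, out$drug_id), , drop = FALSE]
}
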