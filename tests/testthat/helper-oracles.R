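# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: dictionary lookups, term-by-term sums, enumeration.

# Exact-match read counter: assigns a read only when it equals a probe.
oracle_exact_count <- function(reads, panel) {
  counts <- matrix(0L, length(reads), nrow(panel),
                   dimnames = list(names(reads), panel$probe_id))
  for (w in names(reads)) {
    hit <- match(reads[[w]], panel$sequence)
    tab <- table(factor(hit, levels = seq_len(nrow(panel))))
    counts[w, ] <- as.integer(tab)
  }
  counts
}

# Brute-force Hamming distance between two equal-length strings.
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# Term-by-term hypergeometric log-rank statistic over pooled event times.
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chisq = 0, p = 1))
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mw_exact <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x); n <- length(vals)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  center <- n1 * (n - n1) / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Per-batch mean-centering: the direct oracle a location-only batch
# correction should approach on pure additive shifts.
oracle_mean_center <- function(values, batches) {
  out <- values
  gm <- colMeans(values)
  for (b in unique(batches)) {
    i <- batches == b
    out[i, ] <- sweep(values[i, , drop = FALSE], 2,
                      colMeans(values[i, , drop = FALSE]) - gm, "-")
  }
  out
}

# Small well-plate fixture: 2 plates x (2 DMSO + treated wells), values on
# log2 scale chosen by the caller.
make_wells <- function(plate, compound, is_dmso) {
  data.frame(
    well_id = sprintf("W%02d", seq_along(plate)),
    plate_id = plate, compound_id = compound, is_dmso = is_dmso,
    stringsAsFactors = FALSE
  )
}

# Tiny unstructured cell_data: NB counts, gene-specific means, no grouping.
make_null_cells <- function(n_genes = 300, n_cells = 150, seed = 1) {
  sigscreen:::with_seed(seed, {
    mu <- rlnorm(n_genes, log(0.5), 1)
    counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 2),
                     nrow = n_genes,
                     dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                     sprintf("c%04d", seq_len(n_cells))))
    empty <- colSums(counts) == 0
    if (any(empty)) counts[1, empty] <- 1  # guard against zero-total cells
    cell_data(counts)
  })
}
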