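# Shared fixtures and independent oracles used across test files.

# --- independent oracle for the F-score (direct transcription of the
#     between/within dispersion ratio; kept deliberately naive) -------------
oracle_f_score <- function(pos, neg) {
  xb <- mean(c(pos, neg)); xp <- mean(pos); xn <- mean(neg)
  num <- (xp - xb)^2 + (xn - xb)^2
  den <- sum((pos - xp)^2) / (length(pos) - 1) +
    sum((neg - xn)^2) / (length(neg) - 1)
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

# --- brute-force all-pairs neighbour oracle on CA coordinates ---------------
oracle_neighbors <- function(struct, center_resno, radius) {
  a <- struct$atoms[struct$atoms$atom == "CA", ]
  ci <- which(a$resno == center_resno)
  hits <- integer()
  for (j in seq_len(nrow(a))) {
    if (j == ci) next
    d <- sqrt((a$x[j] - a$x[ci])^2 + (a$y[j] - a$y[ci])^2 +
              (a$z[j] - a$z[ci])^2)
    if (d <= radius) hits <- c(hits, a$resno[j])
  }
  sort(hits)
}

oracle_counts <- function(struct, center_resno, radii) {
  a <- struct$atoms[struct$atoms$atom == "CA", ]
  counts <- matrix(0L, 20, length(radii), dimnames = list(AA20, NULL))
  for (k in seq_along(radii)) {
    nb <- oracle_neighbors(struct, center_resno, radii[k])
    aa <- a$aa[match(nb, a$resno)]
    counts[, k] <- as.integer(table(factor(aa, levels = AA20)))
  }
  counts
}

# --- random CA structure with a minimum pair separation ---------------------
random_structure <- function(n, seed, box = 40) {
  set.seed(seed)
  xyz <- matrix(NA_real_, n, 3)
  i <- 1
  while (i <= n) {
    cand <- runif(3, 0, box)
    if (i == 1 ||
        min(sqrt(rowSums((xyz[seq_len(i - 1), , drop = FALSE] -
                          matrix(cand, i - 1, 3, byrow = TRUE))^2))) > 1.0) {
      xyz[i, ] <- cand
      i <- i + 1
    }
  }
  seqs <- paste(sample(AA20, n, replace = TRUE), collapse = "")
  ca_structure(sprintf("rnd%03d", seed), seqs, xyz)
}

# --- Gaussian-blob kinase dataset (structure_only preset) -------------------
# Positive and negative classes are d-dimensional Gaussians separated by
# `sep` along every axis; sep = 0 gives label-free noise.
blob_dataset <- function(n_pos, n_neg, d = 10, sep = 2, seed = 1,
                         group = "blob") {
  set.seed(seed)
  x_pos <- matrix(rnorm(n_pos * d, mean = sep), n_pos, d)
  x_neg <- matrix(rnorm(n_neg * d, mean = 0), n_neg, d)
  sites <- data.frame(
    protein_id = sprintf("b%05d", seq_len(n_pos + n_neg)),
    position = 7L,
    residue = "S",
    kinase_group = group,
    label = c(rep("positive", n_pos), rep("negative", n_neg)),
    stringsAsFactors = FALSE)
  kinase_dataset(group, sites, windows = rep(strrep("A", 6) %+%
                                             "S" %+% strrep("A", 6),
                                             n_pos + n_neg),
                 blocks = list(spatial = rbind(x_pos, x_neg)),
                 preset = "structure_only")
}

`%+%` <- function(a, b) paste0(a, b)

# --- tiny hand-positioned structure: centre SER at origin, ALA at 4 A,
#     LEU at 10 A along x ----------------------------------------------------
toy_structure <- function() {
  ca_structure("toy", "SAL",
               rbind(c(0, 0, 0), c(4, 0, 0), c(10, 0, 0)))
}

# --- raw PDB / DSSP text lines ----------------------------------------------
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", alt = " ") {
  if (nchar(name) < 4) name <- sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, alt, resname, chain, resno, x, y, z, 1, 0)
}

dssp_line <- function(serial, resno, chain, aa, ss, acc) {
  sprintf("%5d%5d %1s %1s  %1s%17s%4d", serial, resno, chain, aa, ss, "",
          acc)
}

dssp_file <- function(lines, path) {
  writeLines(c("==== Secondary Structure Definition ====",
               "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
               lines), path)
  path
}
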