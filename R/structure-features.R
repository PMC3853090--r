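#' Residues within a radial distance of a central residue
#'
#' Distances are measured between per-residue reference atoms: C-alpha by
#' default, C-beta (with C-alpha fallback for glycine) or the nearest pair
#' of heavy atoms. The central residue itself is excluded; residues close
#' in sequence can optionally be excluded to isolate spatially-close-only
#' contacts.
#'
#' @param struct A `phos_structure`.
#' @param center_resno Residue number of the centre.
#' @param radius Radius in Angstroms (> 0).
#' @param chain_id Chain (default: first chain).
#' @param atom_mode `"CA"`, `"CB"` or `"any_heavy"`.
#' @param exclude_seq_window Exclude residues within this many sequence
#'   positions of the centre (0 = keep all).
#' @return Data frame of neighbour residues (`resno`, `aa`, `distance`),
#'   ordered by residue number.
#' @export
spatial_neighbors <- function(struct, center_resno, radius,
                              chain_id = NULL,
                              atom_mode = c("CA", "CB", "any_heavy"),
                              exclude_seq_window = 0L) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(radius > 0)
  res <- chain_residues(struct, chain_id, atom_mode = atom_mode)
  ci <- match(center_resno, res$resno)
  if (is.na(ci)) {
    stop("centre residue ", center_resno, " has no ", atom_mode,
         " reference atom in structure ", struct$structure_id, call. = FALSE)
  }
  d <- residue_distances(res, ci, atom_mode)
  keep <- seq_len(nrow(res)) != ci & d <= radius
  if (exclude_seq_window > 0L) {
    keep <- keep & abs(seq_len(nrow(res)) - ci) > exclude_seq_window
  }
  out <- data.frame(resno = res$resno[keep], aa = res$aa[keep],
                    distance = d[keep], stringsAsFactors = FALSE)
  out[order(out$resno), , drop = FALSE]
}

# Distance from residue `ci` to every residue of `res` under an atom mode.
residue_distances <- function(res, ci, atom_mode) {
  if (atom_mode == "any_heavy") {
    centre <- res$coords[[ci]]
    vapply(seq_len(nrow(res)), function(j) {
      other <- res$coords[[j]]
      d2 <- outer(rowSums(centre^2), rowSums(other^2), "+") -
        2 * tcrossprod(centre, other)
      sqrt(max(0, min(d2)))
    }, 0)
  } else {
    xyz <- as.matrix(res[, c("x", "y", "z")])
    sqrt(rowSums((xyz - matrix(xyz[ci, ], nrow(xyz), 3, byrow = TRUE))^2))
  }
}

#' Spatial amino acid composition around a site
#'
#' For each radius, counts the 20 amino acid types among the residues whose
#' reference atom lies within that distance of the centre (cumulative
#' spheres), and normalises each radius column to relative frequencies.
#' An empty sphere yields an all-zero frequency column.
#'
#' @inheritParams spatial_neighbors
#' @param radii Strictly increasing radii in Angstroms (default 3 to 12).
#' @param cumulative If `FALSE`, counts are per annulus (between consecutive
#'   radii) instead of cumulative spheres.
#' @return Object of class `spatial_aac`: list with `radii`, `counts`
#'   (20 x R integer matrix) and `freq` (20 x R).
#' @export
spatial_aac <- function(struct, center_resno, radii = DEFAULT_RADII,
                        chain_id = NULL,
                        atom_mode = c("CA", "CB", "any_heavy"),
                        exclude_seq_window = 0L, cumulative = TRUE) {
  atom_mode <- match.arg(atom_mode)
  if (is.unsorted(radii, strictly = TRUE)) {
    stop("radii must be strictly increasing", call. = FALSE)
  }
  nb <- spatial_neighbors(struct, center_resno, max(radii),
                          chain_id = chain_id, atom_mode = atom_mode,
                          exclude_seq_window = exclude_seq_window)
  counts <- matrix(0L, nrow = 20L, ncol = length(radii),
                   dimnames = list(AA20, paste0("r", radii)))
  for (k in seq_along(radii)) {
    lo <- if (cumulative || k == 1L) -Inf else radii[k - 1L]
    inside <- nb$aa[nb$distance <= radii[k] & nb$distance > lo]
    counts[, k] <- as.integer(table(factor(inside, levels = AA20)))
  }
  totals <- colSums(counts)
  freq <- counts
  storage.mode(freq) <- "double"
  nz <- totals > 0
  freq[, nz] <- sweep(counts[, nz, drop = FALSE], 2L, totals[nz], "/")
  freq[, !nz] <- 0
  structure(list(radii = radii, counts = counts, freq = freq),
            class = "spatial_aac")
}

#' @export
print.spatial_aac <- function(x, ...) {
  cat(sprintf("<spatial_aac> radii %s Angstroms; %d neighbours at max radius\n",
              paste(range(x$radii), collapse = "-"),
              sum(x$counts[, ncol(x$counts)])))
  invisible(x)
}

#' Flatten a spatial composition into a feature block
#'
#' Frequencies are laid out in (amino acid, radius) order — the 20 values at
#' the smallest radius first.
#'
#' @param saac A [spatial_aac()] object.
#' @return Numeric vector of length `20 * length(radii)` with names
#'   `aa.radius`.
#' @export
spatial_feature_block <- function(saac) {
  out <- as.numeric(saac$freq)
  names(out) <- as.vector(outer(AA20, saac$radii, paste, sep = "."))
  out
}

#' Radial cumulative propensity profile
#'
#' Contrasts the pooled spatial composition of positive sites against that
#' of negative sites: for amino acid type a and radius r the value is
#' `log2` of the pseudocounted positive frequency over the pseudocounted
#' negative frequency. Positive values mark spatial enrichment around true
#' phosphosites, negative values depletion.
#'
#' @param positive_aacs,negative_aacs Lists of [spatial_aac()] objects with
#'   identical radii.
#' @param pseudocount Added per cell (and 20 per column total) before the
#'   ratio (default 0.5).
#' @return Object of class `propensity_profile`: list with `radii` and
#'   `values` (20 x R matrix of log2 ratios).
#' @export
radial_cumulative_propensity <- function(positive_aacs, negative_aacs,
                                         pseudocount = 0.5) {
  if (!length(positive_aacs) || !length(negative_aacs)) {
    stop("both site collections must be non-empty", call. = FALSE)
  }
  radii <- positive_aacs[[1]]$radii
  all_aacs <- c(positive_aacs, negative_aacs)
  same <- vapply(all_aacs, function(s) identical(s$radii, radii), TRUE)
  if (!all(same)) stop("all spatial compositions must share one radii grid",
                       call. = FALSE)
  pool <- function(aacs) Reduce(`+`, lapply(aacs, function(s) s$counts))
  pc <- pseudocount
  logfreq <- function(counts) {
    totals <- colSums(counts)
    log2(sweep(counts + pc, 2L, totals + 20 * pc, "/"))
  }
  values <- logfreq(pool(positive_aacs)) - logfreq(pool(negative_aacs))
  structure(list(radii = radii, values = values),
            class = "propensity_profile")
}

#' @export
print.propensity_profile <- function(x, ...) {
  top <- sort(x$values[, ncol(x$values)], decreasing = TRUE)
  cat(sprintf("<propensity_profile> radii %s; strongest enrichment at max radius: %s (%.2f)\n",
              paste(range(x$radii), collapse = "-"),
              names(top)[1], top[1]))
  invisible(x)
}

#' Export a 20 x R matrix object (spatial composition or propensity) as TSV
#'
#' @param x A `spatial_aac` or `propensity_profile`.
#' @param path Output path.
#' @param what For `spatial_aac`: `"freq"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_radial_table <- function(x, path, what = c("freq", "counts")) {
  what <- match.arg(what)
  mat <- if (inherits(x, "propensity_profile")) x$values else x[[what]]
  df <- data.frame(aa = rownames(mat), mat, check.names = FALSE)
  colnames(df) <- c("aa", paste0("r", x$radii))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
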