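#' Background amino acid distributions
#'
#' @param preset `"uniform"` (default) or `"natural"` (approximate natural
#'   abundance in vertebrate proteomes).
#' @return Named numeric probability vector over [AA20].
#' @export
aa_background <- function(preset = c("uniform", "natural")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    p <- rep(1 / 20, 20)
  } else {
    p <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
           I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 4.0,
           R = 5.5, S = 6.6, T = 5.3, V = 6.9, W = 1.1, Y = 2.9)
    p <- p / sum(p)
  }
  names(p) <- AA20
  p
}

#' Generate random proteins from a background distribution
#'
#' Letters are drawn i.i.d. from `background`; any protein that happens to
#' contain no acceptor residue (S/T/Y) is resampled so every record can
#' carry at least one site.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer range of protein lengths (inclusive).
#' @param background Probability vector over [AA20] (see [aa_background()]).
#' @param seed Integer seed; output is bit-identical across runs.
#' @param id_prefix Identifier prefix (ids are `prefix0001`, ...).
#' @return Named list of [protein_record()] objects.
#' @export
generate_proteins <- function(n_proteins, length_range = c(40L, 60L),
                              background = aa_background(), seed = 1L,
                              id_prefix = "sp") {
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-20 probability vector", call. = FALSE)
  }
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_proteins)) {
    len <- if (length_range[1] == length_range[2]) length_range[1] else
      sample(length_range[1]:length_range[2], 1L)
    for (try in 1:100) {
      letters <- sample(AA20, len, replace = TRUE, prob = background)
      if (any(letters %in% c("S", "T", "Y"))) break
    }
    id <- sprintf("%s%04d", id_prefix, i)
    out[[id]] <- protein_record(id, paste(letters, collapse = ""))
  }
  out
}

#' Plant a sequence motif around a site
#'
#' Replaces letters at given offsets from the site with motif letters, each
#' independently with its stated probability. Offsets falling outside the
#' protein are skipped (with a message).
#'
#' @param protein A [protein_record()].
#' @param site_position 1-based position of the (S/T/Y) site.
#' @param motif_spec Data frame with columns `offset`, `letter`, `prob`.
#' @param seed Integer seed.
#' @return The modified [protein_record()].
#' @export
plant_motif <- function(protein, site_position, motif_spec, seed = 1L) {
  stopifnot(all(c("offset", "letter", "prob") %in% names(motif_spec)))
  centre <- substr(protein$sequence, site_position, site_position)
  if (!centre %in% c("S", "T", "Y")) {
    stop("motif site at position ", site_position, " is '", centre,
         "', not S/T/Y", call. = FALSE)
  }
  set.seed(seed)
  letters <- seq_chars(protein$sequence)
  for (i in seq_len(nrow(motif_spec))) {
    pos <- site_position + motif_spec$offset[i]
    if (pos < 1L || pos > length(letters)) {
      message("motif offset ", motif_spec$offset[i],
              " falls outside protein ", protein$id, "; skipped")
      next
    }
    if (stats::runif(1) <= motif_spec$prob[i]) {
      letters[pos] <- motif_spec$letter[i]
    }
  }
  protein_record(protein$id, paste(letters, collapse = ""))
}

# Uniform random unit vector.
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Self-avoiding biased C-alpha walk. `pull`, when given, is
# list(center, indices, radius): residues `indices` (all > center) are
# steered so their final position lies within `radius` Angstroms of the
# center residue's position. Returns an n x 3 matrix or NULL on failure.
ca_walk_once <- function(n, step, clash_floor, confine_radius, pull) {
  xyz <- matrix(NA_real_, n, 3L)
  xyz[1L, ] <- 0
  target <- NULL
  pulled <- if (is.null(pull)) integer() else sort(pull$indices)
  for (i in 2:n) {
    if (!is.null(pull) && i - 1L == pull$center) {
      target <- xyz[pull$center, ]
    }
    placed <- FALSE
    for (try in 1:250) {
      jitter_sd <- 0.05 + 0.04 * try
      u <- runit()
      if (!is.null(target) && length(pulled)) {
        j <- pulled[pulled >= i][1]
        if (!is.na(j)) {
          d <- sqrt(sum((xyz[i - 1L, ] - target)^2))
          steer <- (i == j) || d > (j - i) * step + pull$radius * 0.5
          if (steer) {
            v <- target - xyz[i - 1L, ]
            nv <- sqrt(sum(v^2))
            dir <- if (nv < 1e-9) runit() else v / nv
            u <- dir + stats::rnorm(3, sd = jitter_sd)
            u <- u / sqrt(sum(u^2))
          }
        }
      }
      cand <- xyz[i - 1L, ] + step * u
      prev <- xyz[seq_len(i - 2L), , drop = FALSE]
      clash <- nrow(prev) > 0 &&
        min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3L,
                                        byrow = TRUE))^2))) < clash_floor
      outside <- !is.null(confine_radius) &&
        sqrt(sum(cand^2)) > confine_radius
      if (outside && !is.null(target)) {
        # the steering sphere may straddle the confinement boundary; let
        # the chain hover near it so clipped spheres stay reachable
        outside <- sqrt(sum((cand - target)^2)) > pull$radius + step
      }
      missed <- !is.null(target) && i %in% pulled &&
        sqrt(sum((cand - target)^2)) > pull$radius
      if (!clash && !outside && !missed) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  xyz
}

#' Generate a toy C-alpha structure for a protein
#'
#' Two coordinate models: an ideal alpha helix (100 degrees twist, 1.5 A
#' rise, 2.3 A radius) or a self-avoiding random walk with 3.8 A steps and
#' a 3.5 A clash floor (candidate steps are resampled on clash). The walk
#' can be confined to a sphere to emulate a compact globular fold, and can
#' steer chosen residues into a sphere around another residue (used to
#' plant spatial enrichments without breaking chain geometry).
#'
#' @param protein A [protein_record()].
#' @param coordinate_model `"ca_random_walk"` or `"ideal_helix"`.
#' @param seed Integer seed.
#' @param step Consecutive C-alpha distance in Angstroms.
#' @param clash_floor Minimum allowed C-alpha pair distance.
#' @param confine_radius Optional confinement sphere radius (walk only).
#' @param pull Optional `list(center, indices, radius)` steering spec
#'   (walk only); all `indices` must exceed `center`.
#' @param max_restarts Whole-walk restarts before giving up.
#' @return A `phos_structure` with one CA per residue.
#' @export
generate_structure <- function(protein,
                               coordinate_model = c("ca_random_walk",
                                                    "ideal_helix"),
                               seed = 1L, step = 3.8, clash_floor = 3.5,
                               confine_radius = NULL, pull = NULL,
                               max_restarts = 200L) {
  coordinate_model <- match.arg(coordinate_model)
  n <- nchar(protein$sequence)
  if (coordinate_model == "ideal_helix") {
    i <- seq_len(n) - 1L
    ang <- i * 100 * pi / 180
    xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  } else {
    if (!is.null(pull)) {
      stopifnot(all(pull$indices > pull$center), pull$radius > 0)
    }
    set.seed(seed)
    xyz <- NULL
    for (r in seq_len(max_restarts)) {
      xyz <- ca_walk_once(n, step, clash_floor, confine_radius, pull)
      if (!is.null(xyz)) break
    }
    if (is.null(xyz)) {
      stop("random walk failed to satisfy clash/steering constraints for ",
           protein$id, " after ", max_restarts, " restarts", call. = FALSE)
    }
  }
  ca_structure(protein$id, protein$sequence, xyz)
}

#' Plant a spatial amino acid enrichment around a site
#'
#' Ensures that `excess` additional residues of type `aa_type`, all more
#' than `flank` sequence positions away from the centre, lie within
#' `radius` Angstroms of the centre residue. Sequence-distal residues whose
#' C-alpha already sits inside the sphere are simply relabelled; when there
#' are not enough of them the chain is re-walked with steered steps
#' (`relocate`) so the chosen residues end up inside the sphere while
#' step-length and clash constraints are preserved exactly.
#'
#' @param struct A single-chain `phos_structure` (CA atoms).
#' @param center_resno Residue number of the site.
#' @param aa_type Amino acid type to enrich (one letter).
#' @param radius Sphere radius in Angstroms.
#' @param excess Number of additional `aa_type` residues required in the
#'   sphere.
#' @param flank Sequence-distance exclusion (planted residues are more than
#'   `flank` positions from the centre).
#' @param seed Integer seed (used by the re-walk).
#' @param step,clash_floor,confine_radius Walk parameters for relocation
#'   (must match how the structure was generated).
#' @return The modified `phos_structure`, with attribute `"planted"` — an
#'   integer vector of the relabelled residue numbers.
#' @export
plant_spatial_enrichment <- function(struct, center_resno, aa_type,
                                     radius, excess, flank = 6L, seed = 1L,
                                     step = 3.8, clash_floor = 3.5,
                                     confine_radius = NULL) {
  stopifnot(aa_type %in% AA20, excess >= 0L)
  if (excess == 0L) {
    attr(struct, "planted") <- integer()
    return(struct)
  }
  res <- chain_residues(struct)
  ci <- match(center_resno, res$resno)
  if (is.na(ci)) stop("centre residue not found", call. = FALSE)
  d <- residue_distances(res, ci, "CA")
  distal <- abs(seq_len(nrow(res)) - ci) > flank
  inside <- d <= radius & seq_len(nrow(res)) != ci
  # residues already inside that only need a new type
  relabelable <- which(distal & inside & res$aa != aa_type)
  relabelable <- relabelable[order(d[relabelable])]
  if (length(relabelable) >= excess) {
    chosen <- res$resno[relabelable[seq_len(excess)]]
    struct$atoms$aa[struct$atoms$resno %in% chosen] <- aa_type
    attr(struct, "planted") <- chosen
    return(struct)
  }
  # relocate: re-walk the chain steering enough distal residues into the
  # sphere to cover the excess on top of everything already inside it
  n_inside_type <- sum(inside & distal & res$aa == aa_type) +
    sum(inside & !distal & res$aa == aa_type)
  need <- excess + n_inside_type
  # pulled residues are spaced 4 apart so the connecting free steps can
  # leave the sphere again, keeping the clash constraint satisfiable
  downstream <- seq(ci + flank + 1L, nrow(res), by = 4L)
  downstream <- downstream[downstream <= nrow(res)]
  if (length(downstream) < need) {
    stop("not enough sequence-distal residues downstream of the site to ",
         "plant ", excess, " '", aa_type, "' residues", call. = FALSE)
  }
  indices <- downstream[seq_len(need)]
  prot <- protein_record(struct$structure_id,
                         paste(chain_residues(struct)$aa, collapse = ""))
  new_struct <- NULL
  for (round in 0:9) {  # deterministic retry rounds on hard geometries
    round_seed <- as.integer((as.numeric(seed) + round * 1000003) %%
                               .Machine$integer.max)
    new_struct <- tryCatch(
      generate_structure(
        prot, "ca_random_walk", seed = round_seed,
        step = step, clash_floor = clash_floor,
        confine_radius = confine_radius,
        pull = list(center = ci, indices = indices, radius = radius)),
      error = function(e) NULL)
    if (!is.null(new_struct)) break
  }
  if (is.null(new_struct)) {
    stop("could not relocate ", need, " residues into a ", radius,
         " Angstrom sphere around residue ", center_resno, call. = FALSE)
  }
  chosen <- res$resno[indices]
  new_struct$atoms$aa[new_struct$atoms$resno %in% chosen] <- aa_type
  attr(new_struct, "planted") <- chosen
  new_struct
}

#' Random per-residue ASA / secondary-structure annotations
#'
#' Draws uninformative relative accessibilities (uniform on `[0, 1]`) and
#' three-state secondary structure (H/E/C with typical proportions) for
#' every residue of every protein. These stand in for predictor output in
#' synthetic benchmarks; they carry no class signal by construction.
#'
#' @param proteins Named list of [protein_record()].
#' @param seed Integer seed.
#' @return Annotation data frame (`protein_id`, `position`, `asa_rel`,
#'   `ss3`).
#' @export
generate_annotations <- function(proteins, seed = 1L) {
  set.seed(seed)
  out <- lapply(proteins, function(p) {
    n <- nchar(p$sequence)
    data.frame(protein_id = p$id, position = seq_len(n),
               asa_rel = stats::runif(n),
               ss3 = sample(c("H", "E", "C"), n, replace = TRUE,
                            prob = c(0.35, 0.20, 0.45)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Configuration for a synthetic kinase benchmark
#'
#' Each group is a list with an optional `motif` (data frame `offset`,
#' `letter`, `prob`) and an optional `spatial` enrichment
#' (`list(aa, radius, excess)`). Defaults emulate a basophilic kinase:
#' arginines at -3/-2 with probability 0.9 and three extra methionines
#' within 6 Angstroms of the site.
#'
#' @param groups Named list of group specs (see above).
#' @param n_pos Positive sites per group (one synthetic protein each).
#' @param protein_length Length of every synthetic protein.
#' @param flank Window flank.
#' @param radii Radii for spatial composition features.
#' @param background Background distribution over [AA20].
#' @param confine_radius Confinement sphere for the C-alpha walk.
#' @param seed Master seed.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(groups = list(
                               PKX = list(
                                 motif = data.frame(offset = c(-3, -2),
                                                    letter = c("R", "R"),
                                                    prob = c(0.9, 0.9)),
                                 spatial = list(aa = "M", radius = 6,
                                                excess = 3))),
                             n_pos = 50L, protein_length = 48L,
                             flank = 6L, radii = DEFAULT_RADII,
                             background = aa_background(),
                             confine_radius = 14, seed = 1L) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  structure(list(groups = groups, n_pos = n_pos,
                 protein_length = protein_length, flank = flank,
                 radii = radii, background = background,
                 confine_radius = confine_radius, seed = seed),
            class = "benchmark_config")
}

# Feature blocks for a set of sites given annotations and structures.
site_feature_blocks <- function(sites, proteins, annotations, structures,
                                flank, radii) {
  n <- nrow(sites)
  windows <- character(n)
  aac_m <- matrix(0, n, 20L)
  asa_m <- matrix(0, n, 2L * flank + 1L)
  ss_m <- matrix(0, n, 3L * (2L * flank + 1L))
  spat_m <- matrix(0, n, 20L * length(radii))
  for (i in seq_len(n)) {
    p <- proteins[[sites$protein_id[i]]]
    pos <- sites$position[i]
    windows[i] <- extract_window(p, pos, flank)
    aac_m[i, ] <- aac(windows[i])
    ann <- annotations[annotations$protein_id == p$id, , drop = FALSE]
    asa_m[i, ] <- encode_asa_window(ann, pos, flank)
    ss_m[i, ] <- encode_ss_window(ann, pos, flank)
    saac <- spatial_aac(structures[[p$id]], pos, radii = radii)
    spat_m[i, ] <- spatial_feature_block(saac)
  }
  list(windows = windows,
       blocks = list(aac = aac_m, asa = asa_m, ss = ss_m, spatial = spat_m))
}

#' Generate an end-to-end synthetic kinase benchmark
#'
#' For every configured group, generates one protein per positive site,
#' forces an acceptor residue mid-sequence, plants the group's sequence
#' motif and spatial enrichment, generates a compact self-avoiding C-alpha
#' structure, draws uninformative ASA/SS annotations, enumerates negatives
#' (all other S/T/Y on the same proteins), and assembles feature blocks
#' under the combined preset. Fully reproducible from the master seed.
#'
#' @param config A [benchmark_config()].
#' @return Named list (one entry per group) of lists with elements
#'   `dataset` (a combined-preset [kinase_dataset()]), `proteins`,
#'   `structures`, `annotations` and `sites`.
#' @export
generate_kinase_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  set.seed(config$seed)
  group_seeds <- sample.int(.Machine$integer.max, length(config$groups))
  flank <- config$flank
  out <- list()
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    gspec <- config$groups[[gi]]
    set.seed(group_seeds[gi])
    seeds <- matrix(sample.int(.Machine$integer.max, 5L * config$n_pos),
                    ncol = 5L)
    proteins <- list()
    structures <- list()
    pos_rows <- vector("list", config$n_pos)
    for (i in seq_len(config$n_pos)) {
      id <- sprintf("%s_%04d", gname, i)
      prot <- generate_proteins(1L, rep(config$protein_length, 2L),
                                config$background, seed = seeds[i, 1],
                                id_prefix = "tmp")[[1]]
      prot <- protein_record(id, prot$sequence)
      set.seed(seeds[i, 2])
      centre <- sample((flank + 10L):(flank + 18L), 1L)
      letters <- seq_chars(prot$sequence)
      letters[centre] <- sample(c("S", "T", "Y"), 1L)
      prot <- protein_record(id, paste(letters, collapse = ""))
      if (!is.null(gspec$motif)) {
        prot <- plant_motif(prot, centre, gspec$motif, seed = seeds[i, 3])
      }
      struct <- generate_structure(prot, "ca_random_walk",
                                   seed = seeds[i, 4],
                                   confine_radius = config$confine_radius)
      if (!is.null(gspec$spatial)) {
        struct <- plant_spatial_enrichment(
          struct, centre, gspec$spatial$aa, gspec$spatial$radius,
          gspec$spatial$excess, flank = flank, seed = seeds[i, 5],
          confine_radius = config$confine_radius)
        planted <- attr(struct, "planted")
        if (length(planted)) {  # keep sequence and structure consistent
          letters <- seq_chars(prot$sequence)
          letters[planted] <- gspec$spatial$aa
          prot <- protein_record(id, paste(letters, collapse = ""))
        }
      }
      proteins[[id]] <- prot
      structures[[id]] <- struct
      pos_rows[[i]] <- data.frame(protein_id = id, position = centre,
                                  residue = substr(prot$sequence, centre,
                                                   centre),
                                  stringsAsFactors = FALSE)
    }
    pos_rows <- do.call(rbind, pos_rows)
    positives <- phospho_sites(pos_rows$protein_id, pos_rows$position,
                               pos_rows$residue, gname, "positive",
                               proteins = proteins)
    negatives <- do.call(rbind, lapply(names(proteins), function(id) {
      build_negative_set(proteins[[id]],
                         positives$position[positives$protein_id == id],
                         kinase_group = gname)
    }))
    sites <- rbind(positives, negatives)
    annotations <- generate_annotations(proteins, seed = group_seeds[gi])
    fb <- site_feature_blocks(sites, proteins, annotations, structures,
                              flank, config$radii)
    dataset <- kinase_dataset(gname, sites, fb$windows, fb$blocks,
                              preset = "combined")
    out[[gname]] <- list(dataset = dataset, proteins = proteins,
                         structures = structures,
                         annotations = annotations, sites = sites)
  }
  out
}

#' Re-declare the feature preset of a dataset
#'
#' The combined-preset dataset generated by [generate_kinase_benchmark()]
#' carries every block, so narrower presets can be derived without
#' recomputation.
#'
#' @param dataset A [kinase_dataset()].
#' @param preset Target preset.
#' @return A [kinase_dataset()] under the new preset.
#' @export
set_preset <- function(dataset, preset) {
  kinase_dataset(dataset$group, dataset$sites, dataset$windows,
                 dataset$blocks, preset = preset)
}

#' Write a benchmark to disk in the package's external formats
#'
#' FASTA sequences, TSV site tables, one PDB file per structure and a TSV
#' annotation table per group, so integration tests can exercise the real
#' readers on generator output.
#'
#' @param benchmark Output of [generate_kinase_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gname in names(benchmark)) {
    g <- benchmark[[gname]]
    gdir <- file.path(dir, gname)
    dir.create(file.path(gdir, "pdb"), recursive = TRUE,
               showWarnings = FALSE)
    write_fasta(g$proteins, file.path(gdir, "proteins.fasta"))
    write_site_table(g$sites, file.path(gdir, "sites.tsv"))
    write_annotation_table(g$annotations, file.path(gdir,
                                                    "annotations.tsv"))
    for (id in names(g$structures)) {
      write_pdb_structure(g$structures[[id]],
                          file.path(gdir, "pdb", paste0(id, ".pdb")))
    }
  }
  invisible(dir)
}
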