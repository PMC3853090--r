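test_that("protein generation is seeded, respects the background and keeps an acceptor", {
  p1 <- generate_proteins(5, c(40, 60), seed = 1)
  p2 <- generate_proteins(5, c(40, 60), seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_proteins(5, c(40, 60), seed = 2)))

  bg <- stats::setNames(rep(0, 20), AA20)
  bg[c("A", "S")] <- 0.5
  only_as <- generate_proteins(10, c(30, 30), background = bg, seed = 3)
  letters <- unlist(lapply(only_as, function(p) seq_chars(p$sequence)))
  expect_setequal(unique(letters), c("A", "S"))
  expect_true(all(vapply(only_as, function(p)
    any(seq_chars(p$sequence) %in% c("S", "T", "Y")), TRUE)))

  expect_error(generate_proteins(1, background = rep(0.1, 20)),
               "probability")
})

test_that("generated letter frequencies match the background within 3 sigma", {
  bg <- aa_background("natural")
  prots <- generate_proteins(1000, c(100, 100), background = bg, seed = 4)
  letters <- unlist(lapply(prots, function(p) seq_chars(p$sequence)))
  n <- length(letters)
  counts <- table(factor(letters, levels = AA20))
  for (a in setdiff(AA20, c("S", "T", "Y"))) {  # acceptors get resampled
    expected <- n * bg[[a]]
    sigma <- sqrt(n * bg[[a]] * (1 - bg[[a]]))
    expect_lt(abs(counts[[a]] - expected), 3 * sigma)
  }
})

test_that("motif planting is probabilistic with the stated rate", {
  prot <- protein_record("p", strrep("A", 20) %+% "S" %+% strrep("A", 20))
  spec1 <- data.frame(offset = -3, letter = "R", prob = 1)
  planted <- plant_motif(prot, 21, spec1, seed = 1)
  expect_equal(substr(planted$sequence, 18, 18), "R")

  spec0 <- data.frame(offset = -3, letter = "R", prob = 0)
  expect_equal(plant_motif(prot, 21, spec0, seed = 1)$sequence,
               prot$sequence)

  p <- 0.7; n <- 1000
  hits <- vapply(seq_len(n), function(s) {
    substr(plant_motif(prot, 21,
                       data.frame(offset = -3, letter = "R", prob = p),
                       seed = s)$sequence, 18, 18) == "R"
  }, TRUE)
  sigma <- sqrt(n * p * (1 - p))
  expect_lt(abs(sum(hits) - n * p), 3 * sigma)

  expect_message(plant_motif(prot, 21, data.frame(offset = 30, letter = "R",
                                                  prob = 1), seed = 1),
                 "skipped")
})

test_that("coordinate models satisfy step-length and clash-floor constraints", {
  prot <- generate_proteins(1, c(20, 20), seed = 5)[[1]]
  helix <- generate_structure(prot, "ideal_helix")
  xyz <- as.matrix(helix$atoms[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))

  prot2 <- generate_proteins(1, c(60, 60), seed = 6)[[1]]
  w1 <- generate_structure(prot2, "ca_random_walk", seed = 7,
                           confine_radius = 14)
  w2 <- generate_structure(prot2, "ca_random_walk", seed = 7,
                           confine_radius = 14)
  expect_identical(w1, w2)
  xyz <- as.matrix(w1$atoms[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(steps - 3.8) < 1e-9))
  dmat <- as.matrix(stats::dist(xyz))
  expect_gte(min(dmat[upper.tri(dmat)]), 3.5)  # brute-force clash check
  expect_true(all(sqrt(rowSums(xyz^2)) <= 14 + 1e-9))
})

test_that("spatial enrichment planting raises the in-sphere count by the excess", {
  prot <- generate_proteins(1, c(48, 48), seed = 8)[[1]]
  centre <- 20L
  for (seed in c(9, 10)) {
    s0 <- generate_structure(prot, "ca_random_walk", seed = seed,
                             confine_radius = 14)
    before <- spatial_aac(s0, centre, radii = 6)$counts["M", 1]
    s1 <- plant_spatial_enrichment(s0, centre, "M", radius = 6, excess = 3,
                                   seed = seed, confine_radius = 14)
    after <- spatial_aac(s1, centre, radii = 6)$counts["M", 1]
    expect_gte(after - before, 3)
    planted <- attr(s1, "planted")
    expect_true(all(abs(planted - centre) > 6))
    # geometry invariants survive planting
    xyz <- as.matrix(s1$atoms[, c("x", "y", "z")])
    expect_true(all(abs(sqrt(rowSums(diff(xyz)^2)) - 3.8) < 1e-9))
    dmat <- as.matrix(stats::dist(xyz))
    expect_gte(min(dmat[upper.tri(dmat)]), 3.5)
  }
  s0 <- generate_structure(prot, "ca_random_walk", seed = 11,
                           confine_radius = 14)
  s_same <- plant_spatial_enrichment(s0, centre, "M", radius = 6,
                                     excess = 0, seed = 1)
  expect_equal(s_same$atoms, s0$atoms)
})

test_that("benchmarks are reproducible, sized to config, and class-disjoint", {
  cfg <- benchmark_config(n_pos = 8, seed = 12)
  b1 <- generate_kinase_benchmark(cfg)
  b2 <- generate_kinase_benchmark(cfg)
  expect_identical(b1$PKX$dataset, b2$PKX$dataset)

  ds <- b1$PKX$dataset
  expect_equal(sum(ds$sites$label == "positive"), 8)
  expect_gt(sum(ds$sites$label == "negative"), 8)
  key <- paste(ds$sites$protein_id, ds$sites$position)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(ncol(ds$blocks$spatial), 200)
})

test_that("written fixtures round-trip through the real readers", {
  cfg <- benchmark_config(n_pos = 4, seed = 13)
  bench <- generate_kinase_benchmark(cfg)
  dir <- withr::local_tempdir()
  write_benchmark(bench, dir)

  prots <- read_fasta(file.path(dir, "PKX", "proteins.fasta"))
  expect_equal(sort(names(prots)),
               sort(names(bench$PKX$proteins)))
  sites <- read_site_table(file.path(dir, "PKX", "sites.tsv"), prots)
  expect_equal(nrow(sites), nrow(bench$PKX$sites))
  ann <- read_annotation_table(file.path(dir, "PKX", "annotations.tsv"))
  expect_equal(nrow(ann), 4 * cfg$protein_length)

  id <- names(prots)[1]
  s <- read_pdb_structure(file.path(dir, "PKX", "pdb",
                                    paste0(id, ".pdb")))
  orig <- bench$PKX$structures[[id]]
  expect_equal(as.matrix(s$atoms[, c("x", "y", "z")]),
               as.matrix(orig$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # a positive site maps onto its own structure with identity 1
  pos1 <- sites[sites$label == "positive" & sites$protein_id == id, ][1, ]
  m <- map_site_to_structure(prots[[id]], pos1, s)
  expect_equal(m$identity, 1)
  expect_equal(m$residue_number, pos1$position)
})

test_that("the pipeline commands run on a simulated benchmark directory", {
  dir <- withr::local_tempdir()
  cfg <- run_config(list(seed = 14, out_dir = file.path(dir, "sim"),
                         n_pos = 6))
  bench <- cmd_simulate(cfg)
  gdir <- file.path(dir, "sim", "PKX")
  run_cfg <- run_config(list(
    sequences = file.path(gdir, "proteins.fasta"),
    sites = file.path(gdir, "sites.tsv"),
    annotations = file.path(gdir, "annotations.tsv"),
    structures_dir = file.path(gdir, "pdb"),
    preset = "combined", seed = 14, repeats = 2, folds = 3,
    out_dir = file.path(dir, "out")))
  paths <- cmd_featurize(run_cfg)
  expect_true(all(file.exists(paths)))
  feat <- utils::read.delim(paths[1])
  expect_equal(sum(grepl("^spatial", names(feat))), 200)

  reports <- suppressMessages(cmd_evaluate(run_cfg))
  expect_true(all(c("sn", "sp", "acc", "pre") %in% names(reports$PKX)))
  model_paths <- cmd_train(run_cfg)
  bundle <- readRDS(model_paths[1])
  expect_equal(bundle$format, "spatialphos-model")
  expect_s3_class(bundle$model, "phos_svm")
})
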