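# minimal hand-built image-level table: 1 plate, wells x fields, given values
toy_table <- function(values_by_well, genotype = NULL, treatment = NULL,
                      feature = "Nuc_Area_001") {
  n_wells <- length(values_by_well)
  if (is.null(genotype)) genotype <- rep("KO", n_wells)
  if (is.null(treatment)) treatment <- rep("VEHICLE", n_wells)
  rows <- lapply(seq_len(n_wells), function(i) {
    v <- values_by_well[[i]]
    data.frame(plate_id = "P01", well = sprintf("A%02d", i),
               subclone_id = "SC1", genotype = genotype[i],
               treatment = treatment[i], concentration_nM = 0,
               field = seq_along(v), x = v)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "x"] <- feature
  out
}

test_that("well aggregation takes the median over fields and ignores NA", {
  tab <- toy_table(list(c(1, 2, 3, 100)))
  expect_equal(aggregate_to_well(tab)[[8]], 2.5)
  expect_equal(aggregate_to_well(toy_table(list(7)))[[8]], 7)
  expect_equal(aggregate_to_well(toy_table(list(c(1, 2, 9, NA))))[[8]], 2)
  expect_equal(aggregate_to_well(tab, statistic = "mean")[[8]], 26.5)
})

test_that("aggregation rejects inconsistent within-well metadata", {
  tab <- toy_table(list(c(1, 2)))
  tab$genotype[2] <- "WT"
  expect_error(aggregate_to_well(tab), "inconsistent metadata.*P01 A01")
})

test_that("normalisation makes anchor wells median 0 / scaled MAD 1 per plate", {
  scr <- small_screen(seed = 13)
  wells <- aggregate_to_well(scr$table)
  norm <- normalize_to_controls(wells)
  for (pl in unique(norm$plate_id)) {
    anchor <- norm$plate_id == pl & norm$genotype == "KO" &
      norm$treatment == "VEHICLE"
    m <- as.matrix(norm[anchor, -(1:7)])
    expect_equal(unname(apply(m, 2, median)), rep(0, ncol(m)), tolerance = 1e-12)
    expect_equal(unname(apply(m, 2, mad)), rep(1, ncol(m)), tolerance = 1e-12)
  }
})

test_that("constant anchor features are flagged degenerate, not divided", {
  scr <- small_screen(seed = 13)
  wells <- aggregate_to_well(scr$table)
  const_feat <- names(wells)[8]
  wells[[const_feat]] <- 3
  norm <- normalize_to_controls(wells)
  expect_true(const_feat %in% attr(norm, "degenerate_features"))
  expect_true(all(norm[[const_feat]] == 0))  # centred only
})

test_that("an additive plate baseline shift leaves WT-KO contrasts unchanged", {
  scr <- simulate_screen(small_design(n_subclones = 1, concentrations = 300),
                         small_params(seed = 17))
  wells <- aggregate_to_well(scr$table)
  shifted <- wells
  shifted$plate_id <- "P99"
  shifted[, -(1:7)] <- shifted[, -(1:7)] + 5
  both <- rbind(wells, shifted)
  norm <- normalize_to_controls(both)
  contrast <- function(pl) {
    sub <- norm[norm$plate_id == pl, ]
    colMeans(sub[sub$genotype == "WT", -(1:7)]) -
      colMeans(sub[sub$genotype == "KO" & sub$treatment == "VEHICLE", -(1:7)])
  }
  expect_equal(contrast("P01"), contrast("P99"), tolerance = 1e-10)
})

test_that("a plate without anchor wells raises an error naming the plate", {
  scr <- small_screen(seed = 13)
  wells <- aggregate_to_well(scr$table)
  wells <- wells[!(wells$plate_id == "P02" & wells$genotype == "KO" &
                   wells$treatment == "VEHICLE"), ]
  expect_error(normalize_to_controls(wells), "P02")
})

test_that("degenerate columns are dropped by the rank rule", {
  base <- toy_table(list(1:4, 2:5, c(0, 1, 0, 2), 4:7, c(2, 4, 6, 9)))
  wells <- aggregate_to_well(base)
  set.seed(1)
  wells$A <- rnorm(5); wells$B <- rnorm(5)
  wells$Constant <- 2
  wells$SumAB <- wells$A + wells$B  # exact linear combination
  res <- drop_degenerate(wells)
  expect_true("Constant" %in% res$dropped$zero_variance)
  expect_true("SumAB" %in% res$dropped$collinear)
  expect_false("A" %in% unlist(res$dropped))
  # rank oracle: retained columns have full column rank
  m <- scale(as.matrix(res$table[, -(1:7)]), scale = FALSE)
  expect_equal(qr(m)$rank, ncol(m))
})

test_that("a seeded full-rank random matrix loses nothing", {
  tab <- toy_table(lapply(1:12, function(i) rep(0, 2)))
  wells <- aggregate_to_well(tab)
  set.seed(42)
  for (j in 1:5) wells[[paste0("F", j)]] <- rnorm(12)
  wells[[8]] <- NULL  # drop the constant toy feature
  res <- drop_degenerate(wells)
  expect_length(unlist(res$dropped), 0)
  expect_equal(qr(scale(as.matrix(wells[, -(1:7)]), scale = FALSE))$rank, 5)
})

test_that("redundant features drop by the mean-absolute-correlation rule", {
  tab <- toy_table(lapply(1:30, function(i) 0))
  wells <- aggregate_to_well(tab)
  wells[[8]] <- NULL
  set.seed(7)
  a <- rnorm(30); c_ <- rnorm(30); d <- rnorm(30)
  wells$FA <- a + 0.2 * c_  # the c_ admixture makes FA more connected than FB
  wells$FB <- a + rnorm(30, 0, 0.05)
  wells$FC <- c_
  wells$FD <- d
  res <- drop_redundant(wells, r_threshold = 0.95)
  # FA has the larger mean |r| to the others, so FA is the one dropped
  mean_fa <- mean(abs(cor(wells$FA, wells[, c("FB", "FC", "FD")])))
  mean_fb <- mean(abs(cor(wells$FB, wells[, c("FA", "FC", "FD")])))
  expect_gt(abs(cor(wells$FA, wells$FB)), 0.95)
  victim <- if (mean_fa > mean_fb) "FA" else "FB"
  expect_equal(res$dropped, victim)
})

test_that("exact duplicates lose one member and orthogonal columns none", {
  tab <- toy_table(lapply(1:10, function(i) 0))
  wells <- aggregate_to_well(tab)
  wells[[8]] <- NULL
  wells$FA <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  wells$FB <- c(1, 1, -1, -1, 1, 1, -1, -1, 1, 1)
  expect_length(drop_redundant(wells)$dropped, 0)
  wells$FA2 <- wells$FA  # exact duplicate; tie broken by later name
  res <- drop_redundant(wells)
  expect_equal(res$dropped, "FA2")
  expect_true("FA" %in% names(res$table))
})

test_that("anova_filter matches aov and flags untestable features", {
  scr <- small_screen(seed = 19)
  wells <- aggregate_to_well(scr$table)
  ctrl <- wells[wells$treatment %in% c("VEHICLE", "UNTREATED"), ]
  grp <- paste(ctrl$genotype, ctrl$treatment)
  rep_ <- anova_filter(ctrl, grp)
  # dual route: stats::aov on a handful of features
  for (f in rep_$feature[c(1, 10, 30)]) {
    fit <- summary(stats::aov(ctrl[[f]] ~ factor(grp)))[[1]]
    i <- match(f, rep_$feature)
    expect_equal(rep_$f[i], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(rep_$p[i], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  expect_true(all(rep_$q >= rep_$p))
  ctrl$Flat_Feature <- 1
  rep2 <- anova_filter(ctrl, grp)
  expect_true("Flat_Feature" %in% rep2$untestable)
  expect_false("Flat_Feature" %in% rep2$feature)
})

test_that("a strong group effect is retained with q near zero", {
  set.seed(3)
  tab <- toy_table(lapply(1:40, function(i) 0),
                   genotype = rep(c("WT", "KO"), each = 20))
  wells <- aggregate_to_well(tab)
  wells[[8]] <- NULL
  wells$Strong <- rnorm(40, rep(c(0, 5), each = 20), 1)
  wells$Nullf <- rnorm(40)
  rep_ <- anova_filter(wells, wells$genotype)
  expect_true("Strong" %in% rep_$significant)
  i <- match("Strong", rep_$feature)
  expect_lt(rep_$q[i], 1e-10)
  # closed-form F for a 2-group comparison equals the squared t statistic
  tt <- t.test(wells$Strong ~ wells$genotype, var.equal = TRUE)
  expect_equal(rep_$f[i], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("groups with fewer than 2 observations are rejected by name", {
  scr <- small_screen(seed = 19)
  wells <- aggregate_to_well(scr$table)[1:5, ]
  expect_error(anova_filter(wells, c("a", "a", "a", "a", "lonely")), "lonely")
})

test_that("BH adjustment equals the brute-force step-up on random p-vectors", {
  set.seed(123)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_step_up(p), tolerance = 1e-12)
  }
})

test_that("the QC pipeline is idempotent on its own output", {
  scr <- small_screen(seed = 23)
  qc <- run_feature_qc(scr$table)
  deg2 <- drop_degenerate(qc$wells)
  expect_length(unlist(deg2$dropped), 0)
  red2 <- drop_redundant(deg2$table)
  expect_length(red2$dropped, 0)
})

test_that("image-level projection reuses well-level normalisation exactly", {
  scr <- small_screen(seed = 23)
  qc <- run_feature_qc(scr$table)
  img <- apply_feature_qc(qc, scr$table)
  expect_equal(names(img)[-(1:7)], qc$retained)
  # aggregating the projected image table reproduces the QC'd well table
  agg <- aggregate_to_well(img)
  expect_equal(as.matrix(agg[, -(1:7)]),
               as.matrix(qc$wells[, -(1:7)]), tolerance = 1e-12)
})
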