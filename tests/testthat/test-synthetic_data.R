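test_that("sem_to_sd reconstructs the per-sample spread", {
  expect_equal(sem_to_sd(0.0, 20), 0.0)
  expect_equal(sem_to_sd(0.1, 20), 0.4472, tolerance = 1e-4)
  expect_equal(sem_to_sd(0.6, 6), 1.4697, tolerance = 1e-4)
  expect_error(sem_to_sd(0.1, 0), "must be >= 1")
})

test_that("packaged group parameters have the published structure", {
  specs <- reference_groups()
  expect_named(specs, c("CTR", "ComplexI", "GlycV", "DMD", "BMD", "Xp21",
                        "LGMD2C", "NCL", "ICU"))
  expect_equal(vapply(specs, `[[`, integer(1), "n"),
               c(CTR = 20L, ComplexI = 12L, GlycV = 7L, DMD = 6L, BMD = 6L,
                 Xp21 = 4L, LGMD2C = 6L, NCL = 6L, ICU = 6L))
  expect_true(specs$CTR$control)
  expect_equal(nrow(marker_panel()), 19L)
  expect_setequal(marker_panel()$compartment, c("mitochondrial", "cytoplasmic"))
  # every ratio constituent exists in the panel
  expect_true(all(c("bF1", "Hsp60", "GAPDH", "LDHA") %in% marker_panel()$name))
  # the absent-myophosphorylase cell is exactly zero
  pm <- specs$GlycV$per_marker
  expect_equal(pm$mean_fold[pm$marker == "PYGM"], 0.0)
  expect_equal(pm$sem[pm$marker == "PYGM"], 0.0)
})

test_that("cohort simulation honors degenerate and exact cells", {
  spec <- cohort_spec(reference_groups(c("CTR", "GlycV")), seed = 11)
  expr <- simulate_cohort(spec, markers = c("PYGM", "NADHs9"))
  expect_identical(expr$PYGM[expr$class_label == "GlycV"], rep(0, 7))
  # zero SEM everywhere -> every sample equals the group mean
  g <- group_spec("X", 5, means = c(a = 2, b = 0.3), sems = c(a = 0, b = 0))
  ctr <- group_spec("CTR", 3, means = c(a = 1, b = 1), sems = c(a = 0, b = 0),
                    control = TRUE)
  e2 <- simulate_cohort(cohort_spec(list(ctr, g), seed = 1))
  expect_identical(e2$a[e2$class_label == "X"], rep(2, 5))
  expect_identical(e2$b[e2$class_label == "X"], rep(0.3, 5))
})

test_that("cohort simulation is deterministic under a fixed seed and leaves the global RNG alone", {
  spec <- cohort_spec(reference_groups(c("CTR", "DMD")), seed = 99)
  set.seed(123); before <- runif(1)
  e1 <- simulate_cohort(spec)
  e2 <- simulate_cohort(spec)
  expect_identical(e1, e2)
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("missing marker parameters name the group and marker", {
  g <- group_spec("DMD", 3, means = c(a = 1), sems = c(a = 0.1))
  ctr <- group_spec("CTR", 3, means = c(a = 1, b = 1), sems = c(a = 0, b = 0),
                    control = TRUE)
  expect_error(simulate_cohort(cohort_spec(list(ctr, g), seed = 1),
                               markers = c("a", "b")),
               "group 'DMD'.*marker 'b'")
})

test_that("simulated draws match the censored-normal generator moments", {
  # controls: mean 1, SEM 0.1, n = 20 -> SD 0.4472; 10,000+ draws
  ctr <- reference_groups("CTR")
  draws <- unlist(lapply(1:500, function(r) {
    simulate_cohort(cohort_spec(ctr, seed = 3000 + r), markers = "bF1")$bF1
  }))
  expect_gte(length(draws), 10000)
  expect_equal(sd(draws), 0.4472, tolerance = 0.03)
  expect_true(all(draws >= 0))
})

test_that("spot tables carry quadruplicates, standards and blanks", {
  spec <- cohort_spec(reference_groups(c("CTR", "DMD")), seed = 5)
  expr <- simulate_cohort(spec, markers = c("bF1", "GAPDH"))
  layout <- array_layout(technical_cv_percent = 0, seed = 2)
  tab <- simulate_spot_table(expr, layout)
  smp <- tab[tab$content_type == "sample", ]
  counts <- table(smp$marker, smp$sample_id)
  expect_true(all(counts == 4L))
  # noiseless: all quadruplicate spots of a sample identical
  spread <- tapply(smp$intensity, paste(smp$marker, smp$sample_id), sd)
  expect_true(all(spread == 0))
  # zero-concentration standard sits at the intercept = blank level
  std0 <- tab[tab$content_type == "standard" & tab$nominal_concentration == 0, ]
  blk <- tab[tab$content_type == "blank", ]
  expect_equal(unique(std0$intensity), unique(blk$intensity))
  expect_error(simulate_spot_table(expr, layout,
                                   data.frame(marker = c("bF1", "GAPDH"),
                                              slope = c(-1, 2), intercept = 0)),
               "slopes must be > 0")
  # deterministic under the layout seed
  layout2 <- array_layout(seed = 7)
  expect_identical(simulate_spot_table(expr, layout2),
                   simulate_spot_table(expr, layout2))
})

test_that("spec constructors reject invalid configurations", {
  expect_error(group_spec("CTR", 3, means = c(a = 1.2), sems = c(a = 0.1),
                          control = TRUE), "mean fold 1.0")
  expect_error(group_spec("g", 3, means = c(a = -1), sems = c(a = 0.1)),
               "negative mean")
  g <- group_spec("g", 3, means = c(a = 1), sems = c(a = 0.1))
  expect_error(cohort_spec(list(g), seed = 1), "control")
  expect_error(array_layout(standard_concentrations = c(0.5, 1)),
               "concentration 0")
})
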