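# The synthetic generator: preset fidelity, determinism, counting
# statistics, and ion-image scenes.

# Frozen copy of the published 7-day per-cluster parameters used by the
# day7 preset (means of the five clustering ratios, components a-e, and
# component sizes) — kept independent of the package's internal table.
frozen_day7 <- list(
  n = c(a = 443, b = 136, c = 106, d = 32, e = 60),
  mean = rbind(
    r13C  = c(0.0304, 0.0499, 0.2687, 0.0694, 0.1323),
    r15N  = c(0.0105, 0.0157, 0.0532, 0.0217, 0.1001),
    r33S  = c(0.0151, 0.0150, 0.0306, 0.0078, 0.2229),
    rC_CN = c(0.3736, 0.7612, 0.5187, 0.4769, 0.2759),
    rS_CN = c(0.0886, 0.1509, 0.1188, 0.3125, 0.0690)),
  sd = rbind(
    r13C  = c(0.0298, 0.0385, 0.1112, 0.0397, 0.0850),
    r15N  = c(0.0105, 0.0100, 0.0125, 0.0103, 0.0162),
    r33S  = c(0.0109, 0.0102, 0.0249, 0.0016, 0.0899),
    rC_CN = c(0.1042, 0.1953, 0.1529, 0.2435, 0.1203),
    rS_CN = c(0.0193, 0.0326, 0.0275, 0.0815, 0.0193)))

test_that("presets carry the published parameters verbatim", {
  spec <- mixture_spec("day7")
  comp <- spec$components
  expect_equal(comp$name, letters[1:5])
  expect_equal(comp$n, unname(frozen_day7$n))
  for (rc in rownames(frozen_day7$mean)) {
    expect_equal(comp[[paste0("mean_", rc)]], unname(frozen_day7$mean[rc, ]),
                 label = rc)
    expect_equal(comp[[paste0("sd_", rc)]], unname(frozen_day7$sd[rc, ]),
                 label = paste(rc, "sd"))
  }
  # condition sizes across presets
  sizes <- vapply(c("day2", "day7", "day10", "NL", "K"),
                  function(p) sum(mixture_spec(p)$components$n), numeric(1))
  expect_equal(unname(sizes), c(665, 777, 760, 645, 268))
  expect_equal(sum(sizes[c("day2", "day7", "day10")]), 2202)
  expect_equal(sum(sizes), 3115)
  # the 10-day condition has no component b
  expect_false("b" %in% mixture_spec("day10")$components$name)
})

test_that("ratio generation is deterministic and respects the floor and sizes", {
  a <- generate_ratio_table("day7", seed = 99)
  b <- generate_ratio_table("day7", seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a$ratios), 777)
  expect_equal(unname(table(a$truth$component)[letters[1:5]]),
               unname(frozen_day7$n), ignore_attr = TRUE)
  expect_true(all(as.matrix(a$ratios[c("r13C", "r15N", "r33S", "r34S",
                                       "rC_CN", "rS_CN")]) >= 1e-6))
  # sd = 0 component: all rows equal the mean
  comp <- data.frame(name = "z", n = 5,
                     p_gamma = 1, p_delta = 0, p_unknown = 0)
  for (rc in c("r13C", "r15N", "r33S", "r34S", "rC_CN", "rS_CN")) {
    comp[[paste0("mean_", rc)]] <- 0.25
    comp[[paste0("sd_", rc)]] <- 0
  }
  z <- generate_ratio_table(mixture_spec("custom", comp), seed = 1)
  expect_true(all(as.matrix(z$ratios["r13C"]) == 0.25))
  expect_error(mixture_spec("custom", transform(comp, n = 0)), "no ROIs")
})

test_that("sample means track the generating (truncated) means within the CLT bound", {
  # resampling below the floor makes the generating law a left-truncated
  # normal; its mean is mu + sd * phi(a)/(1 - Phi(a)), a = (floor - mu)/sd
  trunc_mean <- function(mu, sd, floor = 1e-6) {
    a <- (floor - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  for (s in c(2, 71)) {
    sim <- generate_ratio_table("day7", seed = s)
    for (comp_name in c("a", "c", "e")) {
      idx <- sim$truth$component == comp_name
      j <- match(comp_name, letters)
      for (rc in c("r15N", "r33S", "rC_CN")) {
        mu <- trunc_mean(frozen_day7$mean[rc, j], frozen_day7$sd[rc, j])
        bound <- 4 * frozen_day7$sd[rc, j] / sqrt(sum(idx))
        expect_lt(abs(mean(sim$ratios[[rc]][idx]) - mu), bound + 1e-9)
      }
    }
  }
})

test_that("count expectations invert the ratio definitions exactly", {
  sim <- generate_ratio_table("day7", seed = 13)
  exact <- generate_count_table(sim$ratios, total_cn = 1e6, poisson = FALSE)
  r2 <- compute_ratios(exact)
  expect_equal(nrow(r2), nrow(sim$ratios))
  for (rc in c("r13C", "r15N", "r33S", "r34S", "rC_CN", "rS_CN"))
    expect_equal(r2[[rc]], sim$ratios[[rc]], tolerance = 1e-9, label = rc)
  # r15N = 0 gives zero expected 15N12C counts
  one <- sim$ratios[1, ]; one$r15N <- 0
  expect_equal(generate_count_table(one, 1e4, poisson = FALSE)$nc15, 0)
})

test_that("poisson counts recover generating ratios within counting error", {
  sim <- generate_ratio_table("day7", seed = 21)
  tab <- generate_count_table(sim$ratios, total_cn = 1e6, seed = 21)
  r2 <- compute_ratios(tab)
  expect_equal(nrow(r2), nrow(sim$ratios))
  exact <- generate_count_table(sim$ratios, total_cn = 1e6, poisson = FALSE)
  # 13C/12C within 4 sigma of the generating ratio for >= 99% of ROIs,
  # sigma from Poisson propagation of the minor isotope count
  sigma <- sim$ratios$r13C / sqrt(exact$c13)
  frac <- mean(abs(r2$r13C - sim$ratios$r13C) <= 4 * sigma)
  expect_gte(frac, 0.99)
})

test_that("scenes place cells cleanly and support the full pipeline", {
  # zero background, one coccus: counts only within the mask disk
  comp <- data.frame(name = "c1", n = 1, morphology = "coccus",
                     p_gamma = 1, p_delta = 0, p_unknown = 0)
  for (rc in c("r13C", "r15N", "r33S", "r34S", "rC_CN", "rS_CN")) {
    comp[[paste0("mean_", rc)]] <- 0.1
    comp[[paste0("sd_", rc)]] <- 0.01
  }
  sc <- generate_ion_scene(
    scene_spec(pixels = 48, n_cells = 1, n_planes = 2, background_cn = 0),
    mixture_spec("custom", comp), seed = 5)
  tot <- apply(sc$stack$counts, c(3, 4), sum)
  expect_true(all(tot[sc$mask == 0] == 0))
  expect_gt(sum(tot[sc$mask == 1]), 0)
  # determinism
  sc2 <- generate_ion_scene(
    scene_spec(pixels = 48, n_cells = 1, n_planes = 2, background_cn = 0),
    mixture_spec("custom", comp), seed = 5)
  expect_identical(sc$stack$counts, sc2$stack$counts)
  # drift (1, 0) per plane: alignment recovers the cumulative shifts
  scd <- generate_ion_scene(
    scene_spec(pixels = 64, n_cells = 6, n_planes = 3, drift = c(1, 0)),
    "day7", seed = 8)
  sh <- align_planes(scd$stack)
  expect_equal(unname(sh[, "dy"]), c(0L, 1L, 2L))
  expect_equal(unname(sh[, "dx"]), c(0L, 0L, 0L))
  # end-to-end on a drift-free scene: per-cell 13C/12C within 4 sigma
  sc3 <- generate_ion_scene(
    scene_spec(pixels = 96, n_cells = 10, n_planes = 2,
               cn_per_cell = 3e5), "day7", seed = 14)
  pp <- preprocess_stack(sc3$stack, mask = sc3$mask, tau = NULL,
                         align = FALSE)
  r <- compute_ratios(pp$table)
  truth <- sc3$truth[match(r$roi_id, sc3$truth$roi_id), ]
  c13_expect <- truth$rC_CN * 3e5 * truth$r13C / (1 + truth$r13C)
  sigma <- truth$r13C / sqrt(c13_expect)
  # background adds a small natural-abundance bias; allow it on top
  expect_true(all(abs(r$r13C - truth$r13C) <= 4 * sigma + 0.005))
  # 30 non-touching cells are recovered by automatic ROI extraction
  sc4 <- generate_ion_scene(scene_spec(pixels = 160, n_cells = 30,
                                       n_planes = 1), "day7", seed = 2)
  auto <- preprocess_stack(sc4$stack, tau = NULL, align = FALSE,
                           min_area_px = 5)
  expect_equal(nrow(auto$table), 30)
})
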