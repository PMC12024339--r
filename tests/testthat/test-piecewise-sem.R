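test_that("the three pathway specifications encode the intended graphs", {
  p1 <- pathway_spec(1)
  expect_true(all(c("ann_min_temp", "tnz_b", "body_length") %in% p1$nodes))
  expect_equal(nrow(p1$edges[p1$edges$from == "ann_min_temp", ]), 2)
  p2 <- pathway_spec(2)
  expect_true(any(p2$edges$from == "tnz_b" & p2$edges$to == "body_length"))
  p3 <- pathway_spec(3)
  expect_equal(nrow(p3$correlated), 1)
  expect_error(pathway_spec(4))
})

test_that("the 3-node pathway-1 core yields exactly one claim", {
  core <- list(nodes = c("ann_min_temp", "tnz_b", "body_length"),
               edges = data.frame(
                 from = c("ann_min_temp", "ann_min_temp"),
                 to = c("body_length", "tnz_b")))
  claims <- basis_set(core)
  expect_length(claims, 1)
  expect_setequal(c(claims[[1]]$x, claims[[1]]$response),
                  c("tnz_b", "body_length"))
  expect_equal(claims[[1]]$cond, "ann_min_temp")
})

test_that("a saturated graph has an empty basis and a cyclic graph errors", {
  full <- list(nodes = c("a", "b", "c"),
               edges = data.frame(from = c("a", "a", "b"),
                                  to = c("b", "c", "c")))
  expect_length(basis_set(full), 0)
  cyc <- list(nodes = c("a", "b"),
              edges = data.frame(from = c("a", "b"), to = c("b", "a")))
  expect_error(basis_set(cyc), "cyclic")
})

test_that("a 4-node chain produces the three downstream-conditioned claims", {
  chain <- list(nodes = c("A", "B", "C", "D"),
                edges = data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "D")))
  claims <- basis_set(chain)
  lab <- vapply(claims, function(cl)
    paste0(cl$x, "_", cl$response, "|", paste(cl$cond, collapse = ",")), "")
  expect_setequal(lab, c("A_C|B", "A_D|C", "B_D|C"))
})

test_that("every emitted claim is d-separated and covers each testable pair (graphs up to 4 nodes)", {
  for (k in 2:4) {
    for (edges in all_dags(k)) {
      nodes <- paste0("N", seq_len(k))
      claims <- basis_set(list(nodes = nodes, edges = edges))
      exo <- nodes[!nodes %in% edges$to]
      for (cl in claims) {
        expect_true(dsep_oracle(nodes, edges, cl$x, cl$response, cl$cond))
      }
      ## coverage: all non-adjacent pairs except exogenous-exogenous ones
      pairs <- t(combn(nodes, 2))
      adj <- apply(pairs, 1, function(p)
        any((edges$from == p[1] & edges$to == p[2]) |
            (edges$from == p[2] & edges$to == p[1])))
      expected <- sum(!adj & !(pairs[, 1] %in% exo & pairs[, 2] %in% exo))
      expect_length(claims, expected)
    }
  }
})

test_that("Fisher's C follows its closed form and guards its domain", {
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$fisher_c, -4 * log(0.5), tolerance = 1e-10)
  expect_equal(fc$fisher_c, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4)
  one <- fishers_c(1.0)
  expect_equal(one$fisher_c, 0)
  expect_equal(one$p_value, 1)
  expect_error(fishers_c(c(0.5, 0)), "decisively violated")
  expect_error(fishers_c(1.2), "in \\(0, 1\\]")
})

test_that("Fisher's C is permutation-invariant and monotone in each p-value", {
  p <- c(0.1, 0.4, 0.8)
  expect_identical(fishers_c(p)$fisher_c, fishers_c(rev(p))$fisher_c)
  base <- fishers_c(p)$fisher_c
  for (i in seq_along(p)) {
    lower <- p; lower[i] <- p[i] / 2
    expect_gt(fishers_c(lower)$fisher_c, base)
  }
})

test_that("SEM AIC is Fisher's C plus twice the parameter count", {
  expect_equal(sem_aic(7.70, 10), 27.70)
  expect_equal(sem_aic(8.36, 10), 28.36)
  expect_equal(sem_aic(7.70, 11), 29.70)
  expect_equal(sem_aic(0, 0), 0)
  expect_error(sem_aic(-1, 3))
  expect_error(sem_aic(2, 2.5))
})

test_that("standardized estimates rescale by the SD ratio", {
  expect_equal(standardized_estimate(2, 1, 2), 1)
  ## on already-standardized data the natural slope is the estimate
  expect_equal(standardized_estimate(0.37, 1, 1), 0.37)
  expect_error(standardized_estimate(1, 1, 0), "positive")
})

test_that("pathway fitting returns ranked, internally consistent fits", {
  cfg <- synth_config(n_per_site_year = 15, seed = 211)
  sim <- simulate_study(cfg)
  filtered <- suppressMessages(filter_records(sim$records))
  clim <- spatial_climate_table(sim$climate)
  tnz <- sim$truth$sites[, c("site", "tnz_b")]
  fits <- fit_pathways(filtered, clim, tnz)
  expect_length(fits, 3)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_true(all(diff(aics) >= 0))
  for (f in fits) {
    expect_equal(f$aic - f$fisher_c, 2 * f$K) # AIC - C = 2K exactly
    expect_equal(f$df, 2 * nrow(f$claims))
    expect_true(all(f$claims$p_value > 0 & f$claims$p_value <= 1))
  }
  Ks <- vapply(fits, `[[`, numeric(1), "K")
  ps <- vapply(fits, `[[`, numeric(1), "pathway")
  expect_equal(sort(Ks), c(10, 11, 11))
  expect_equal(Ks[ps == 1], 10)
  ## pathways 2 and 3 share the same claim set, hence the same C
  expect_equal(fits[[which(ps == 2)]]$fisher_c,
               fits[[which(ps == 3)]]$fisher_c, tolerance = 1e-9)
  ## the strong generating Temp -> TNZ_b path shows up standardized
  f1 <- fits[[which(ps == 1)]]
  path_tnz <- f1$paths[f1$paths$edge == "ann_min_temp -> tnz_b", ]
  expect_lt(path_tnz$std_estimate, -0.8)
  ## pathway 3 reports the residual correlation as its own path
  f3 <- fits[[which(ps == 3)]]
  expect_true("tnz_b <-> body_length" %in% f3$paths$edge)
})

test_that("a direct TNZ-to-length effect is detected when truly present", {
  ## generate under pathway 2: length depends on tnz_b given temperature
  set.seed(223)
  rej <- 0
  n_rep <- 20
  for (r in 1:n_rep) {
    temps <- runif(9, 10, 14)
    tnzb <- 6.1 - 0.34 * temps + rnorm(9, 0, 0.15)
    d <- make_records(20, paste0("S", 1:9), temps,
                      site_re = rnorm(9, 0, 0.3))
    d$tnzb_true <- tnzb[match(d$site, paste0("S", 1:9))]
    ## inject a strong direct TNZ effect on length
    d$body_length <- d$body_length - 8 * d$tnzb_true
    clim <- data.frame(site = paste0("S", 1:9), ann_min_temp = temps)
    tnz <- data.frame(site = paste0("S", 1:9), tnz_b = tnzb)
    f1 <- fit_pathways(d, clim, tnz, pathways = 1)[[1]]
    rej <- rej + (f1$claims$p_value[grepl("tnz_b _\\|\\|_ body_length",
                                          f1$claims$claim)] < 0.05)
  }
  expect_gt(rej / n_rep, 0.5)
})
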