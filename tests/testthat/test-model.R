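test_that("variable counts enumerate the index sets", {
  # |I|=4, |J|=3, |K|=2, |L|=2, |W|=2:
  # 6 xTC + 4 xAD + 12 z + 16 y + 16 v + 16 u = 70 binaries
  inst <- make_small_instance(13, n_nodes = 4, n_sites = 3, n_depots = 2)
  dem <- array(1, dim = c(4, 2, 2),
               dimnames = list(inst$region$nodes$id,
                               c("type1", "type2"), NULL))
  scen <- scenario_set(c(0.6, 0.4), dem)
  m <- build_deterministic_equivalent(inst$region, inst$cov, scen,
                                      small_config())
  expect_equal(nrow(m$vars), 70)
  expect_equal(sum(m$vars$role == "xTC"), 6)
  expect_equal(sum(m$vars$role == "z"), 12)
  # the air indicator for non-severe demand is fixed off
  expect_equal(sum(m$vars$fixed %in% 0 & m$vars$role == "u"), 8)
})

test_that("every constraint family is emitted with its tag", {
  inst <- make_small_instance(14, n_nodes = 4, n_sites = 3, n_depots = 2)
  m <- build_deterministic_equivalent(inst$region, inst$cov, inst$scen,
                                      small_config(volume = TRUE))
  tags <- vapply(m$cons, `[[`, "", "tag")
  expect_setequal(unique(tags), as.character(2:14))
  nW <- 3; nI <- 4; nJ <- 3; nK <- 2
  expect_equal(sum(tags == "2"), 1)
  expect_equal(sum(tags == "3"), nJ)
  expect_equal(sum(tags == "6"), nJ * nK * 2)
  expect_equal(sum(tags == "8"), nI * 2 * nW)
  expect_equal(sum(tags == "10"), nI * nW)       # severe type only
  expect_equal(sum(tags == "11"), 2)
  expect_equal(sum(tags == "12"), nJ * 2 * nW)   # per site, type, scenario
  expect_equal(sum(tags == "14"), nK * nW)
})

test_that("a zero budget cascades to a zero optimum", {
  inst <- make_small_instance(15)
  cfg <- small_config(p_TC = 0, p_AD = 0)
  sol <- solve_model(build_model(inst$region, inst$cov, inst$scen, cfg))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
  expect_equal(nrow(sol$x_TC), 0)
  expect_true(all(!sol$y))
})

test_that("the construction variant drops the per-type cap family", {
  inst <- make_small_instance(16)
  cfg <- small_config("CM")
  m <- build_model(inst$region, inst$cov, inst$scen, cfg)
  tags <- vapply(m$cons, `[[`, "", "tag")
  expect_false("11" %in% tags)
  expect_true(all(is.na(m$vars$fixed[m$vars$role == "xTC"])))
})

test_that("the benchmark variant fixes exactly the existing designations", {
  inst <- make_small_instance(17, n_sites = 5)
  m <- build_model(inst$region, inst$cov, inst$scen, small_config("BM"))
  fixed_tc <- which(m$vars$fixed %in% 1 & m$vars$role == "xTC")
  expect_equal(length(fixed_tc), length(existing_sites(inst$region)))
  fixed_ad <- which(m$vars$fixed %in% 1 & m$vars$role == "xAD")
  expect_equal(length(fixed_ad), length(existing_depots(inst$region)))

  # benchmark needs designations to exist
  bare <- make_small_instance(18, designations = FALSE)
  expect_error(build_model(bare$region, bare$cov, bare$scen,
                           small_config("BM")), "existing designations")
})

test_that("zero-headroom improvement equals the benchmark optimum", {
  for (seed in c(21, 22, 23)) {
    inst <- make_small_instance(seed)
    bm <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                  small_config("BM")))
    im0 <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                   small_config("IM", alpha = 0)))
    expect_identical(im0$objective, bm$objective)
    expect_identical(im0$status, bm$status)
  }
})

test_that("improvement headroom raises the budget right-hand sides", {
  inst <- make_small_instance(19)
  cfg <- small_config("IM", alpha = 2, mu = c(1, 1))
  m <- build_model(inst$region, inst$cov, inst$scen, cfg)
  tags <- vapply(m$cons, `[[`, "", "tag")
  expect_equal(m$cons[[which(tags == "2")]]$rhs, cfg$p_TC + 2)
  expect_equal(m$cons[[which(tags == "4")]]$rhs, cfg$p_AD + 2)
  r11 <- m$cons[tags == "11"]
  expect_equal(vapply(r11, `[[`, 0, "rhs"), cfg$r + cfg$mu)
})

test_that("LP export writes a readable model with tagged rows", {
  inst <- make_small_instance(20, n_nodes = 3, n_sites = 2, n_depots = 1)
  m <- build_model(inst$region, inst$cov, inst$scen, small_config())
  f <- withr::local_tempfile(fileext = ".lp")
  write_lp(m, f)
  txt <- readLines(f)
  expect_true(any(txt == "Maximize"))
  expect_true(any(grepl("^ c9_", txt)))
  expect_true(any(txt == "Binary"))
})

test_that("YAML configurations round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(p_TC = 10, p_AD = 2, r = c(1, 9), S = 45,
                        variant = "IM", alpha_TC = 3), f)
  cfg <- read_model_config(f)
  expect_equal(cfg$p_TC, 10)
  expect_equal(cfg$S, 45)
  expect_equal(cfg$alpha_TC, 3)
  expect_equal(cfg$V_min, c(1, 1))  # defaults fill the gaps
  yaml::write_yaml(list(p_TC = 5, nonsense = 1), f)
  expect_error(read_model_config(f), "unknown configuration key")
})
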