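test_that("yule trees are reproducible and well-formed", {
  t1 <- simulate_yule_tree(36, birth_rate = 1, seed = 11)
  t2 <- simulate_yule_tree(36, birth_rate = 1, seed = 11)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 36L)
  expect_true(all(t1$edge.length > 0))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_yule_tree(0), "n_tips")
})

test_that("single-tip tree has an exponential waiting-time depth", {
  tr <- simulate_yule_tree(1, birth_rate = 2, seed = 5)
  expect_equal(ape::Ntip(tr), 1L)
  expect_gt(sum(tr$edge.length), 0)
})

test_that("mean tree depth matches the pure-birth closed form", {
  # depth = sum of Exp(b*k) waits, k = 2..n: E = sum 1/(bk) and
  # Var = sum 1/(bk)^2 -- an independent closed-form oracle
  n <- 8; b <- 1.5; reps <- 300
  expected <- sum(1 / (b * 2:n))
  v <- sum(1 / (b * 2:n)^2)
  set.seed(42)
  depths <- replicate(reps, {
    tr <- simulate_yule_tree(n, birth_rate = b)
    max(ape::node.depth.edgelength(tr))
  })
  expect_lt(abs(mean(depths) - expected), 3 * sqrt(v / reps))
})

test_that("niche profiles respect guild structure", {
  set.seed(7)
  tree <- simulate_yule_tree(36)
  sc <- scenario_config()
  niches <- make_niches(tree, sc)
  for (prof in c(niches$before, niches$after)) {
    expect_equal(sum(prof$preference), 1, tolerance = 1e-12)
    expect_true(all(prof$preference >= 0))
  }
  # specialists confined to their clade, zero mass outside
  for (id in c("cuc1", "cuc2", "cuc3")) {
    outside <- setdiff(names(niches$before[[id]]$preference),
                       niches$clades$cucurbit)
    expect_equal(unname(niches$before[[id]]$preference[outside]),
                 rep(0, length(outside)))
  }
  sol_out <- setdiff(names(niches$before$sol1$preference),
                     niches$clades$solanaceae)
  expect_equal(sum(niches$before$sol1$preference[sol_out]), 0)
  # generalists span >= 3 families
  for (id in c("gen1", "gen2", "gen3")) {
    supp <- names(which(niches$before[[id]]$preference > 0))
    expect_gte(length(unique(niches$families[supp])), 3L)
  }
  # invader exists only after, and shares no host with any specialist
  expect_null(niches$before$invader)
  inv <- names(which(niches$after$invader$preference > 0))
  expect_length(intersect(inv, c(niches$clades$cucurbit,
                                 niches$clades$solanaceae)), 0)
})

test_that("contraction concentrates generalist diets, identity at 1", {
  set.seed(8)
  tree <- simulate_yule_tree(36)
  n1 <- make_niches(tree, scenario_config(contraction_factor = 1))
  for (id in c("gen1", "gen2", "gen3")) {
    expect_equal(n1$after[[id]]$preference, n1$before[[id]]$preference)
  }
  # monotone: smaller contraction factor => smaller true after-period Dalpha
  p <- n1$before$gen1$preference
  contract <- function(p, cf) {
    q <- p^(1 / cf)
    q / sum(q)
  }
  d <- vapply(c(0.3, 0.5, 0.8, 1), function(cf)
    alpha_diversity(contract(p, cf)), 0)
  expect_true(all(diff(d) >= -1e-12))
  # specialists never change
  set.seed(8)
  tree2 <- simulate_yule_tree(36)
  n05 <- make_niches(tree2, scenario_config(contraction_factor = 0.5))
  expect_equal(n05$after$cuc1$preference, n05$before$cuc1$preference)
})

test_that("an 8-host uniform generalist contracted to its top 4 hosts drops toward Dalpha 4", {
  p <- setNames(c(rep(0.125, 8), rep(0, 4)), paste0("t", 1:12))
  expect_equal(alpha_diversity(p), 8)
  top4 <- setNames(c(rep(0.25, 4), rep(0, 8)), paste0("t", 1:12))
  expect_equal(alpha_diversity(top4), 4)
  # a smooth power contraction of a near-uniform profile moves Dalpha down
  q <- setNames(c(0.2, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05, 0.05, rep(0, 4)),
                paste0("t", 1:12))
  expect_lt(alpha_diversity((q^2) / sum(q^2)), alpha_diversity(q))
})

test_that("simulated counts follow the configured model", {
  set.seed(10)
  tree <- simulate_yule_tree(36)
  sc <- scenario_config(samples_per_plant = c(30L, 30L))
  niches <- make_niches(tree, sc)
  ds <- simulate_samples(niches, sc)
  cm <- hostshift:::count_matrix(ds, "before")
  # zero preference => zero counts, always (invader before invasion)
  expect_equal(sum(cm[, "invader"]), 0)
  for (id in c("cuc1", "sol1")) {
    off <- ds$samples$plant_id[ds$samples$period == "before"] %in%
      names(which(niches$before[[id]]$preference == 0))
    expect_equal(sum(cm[off, id]), 0)
  }
})

test_that("poisson sampling hits the configured mean load on the top host", {
  # one fly, two plants, uniform preference: both hosts get the full load
  tips <- c("t1", "t2")
  prof <- list(f1 = list(fly_id = "f1", guild = "generalist",
                         preference = setNames(c(0.5, 0.5), tips),
                         mean_load = 3))
  niches <- list(before = prof, after = prof,
                 families = setNames(c("famA", "famB"), tips))
  sc <- scenario_config(
    n_plants = 2,
    flies = tibble::tibble(fly_id = "f1", guild = "generalist",
                           clade = "none"),
    samples_per_plant = c(2500L, 2500L), mean_load = 3)
  set.seed(3)
  ds <- simulate_samples(niches, sc)
  x <- hostshift:::count_matrix(ds, "before")[, "f1"]
  n <- length(x)
  expect_equal(n, 5000L)
  expect_lt(abs(mean(x) - 3), 3 * sqrt(3 / n))
})

test_that("datasets are byte-identical under a fixed seed", {
  s1 <- simulate_invasion_scenario(seed = 21)
  s2 <- simulate_invasion_scenario(seed = 21)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(s1$dataset, p1)
  write_samples(s2$dataset, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("true indices evaluate the closed forms", {
  prof <- function(v) list(fly_id = "x", guild = "g",
                           preference = v / sum(v), mean_load = 1)
  p4 <- setNames(rep(1, 4), paste0("t", 1:4))
  niches <- list(
    before = list(a = prof(p4), b = prof(p4),
                  c = prof(setNames(c(1, 0, 0, 0), paste0("t", 1:4))),
                  d = prof(setNames(c(1, 1, 0, 0), paste0("t", 1:4)))),
    after = NULL)
  ti <- true_indices(niches)
  expect_equal(ti$alpha$d_alpha[ti$alpha$fly_id == "a"], 4)
  t_ab <- ti$pairs$turnover[ti$pairs$fly_i == "a" & ti$pairs$fly_k == "b"]
  expect_equal(t_ab, 0)
  t_cd <- ti$pairs$turnover[ti$pairs$fly_i == "c" & ti$pairs$fly_k == "d"]
  expect_lt(abs(t_cd - 0.240806), 1e-6)
})

test_that("the full pipeline ranks generalists above clade specialists", {
  ok <- 0L
  n_seeds <- 6L
  for (seed in seq_len(n_seeds)) {
    sc <- simulate_invasion_scenario(seed = seed)
    cfg <- run_config(bootstrap_reps = 200, seed = seed)
    ds <- filter_plants(sc$dataset, cfg)
    rep <- suppressWarnings(bootstrap_indices(ds, "before", config = cfg))
    a <- rep$alpha
    gen <- a$d_alpha_mean[a$fly_id %in% c("gen1", "gen2", "gen3")]
    spc <- a$d_alpha_mean[a$fly_id %in% c("cuc1", "cuc2", "cuc3", "sol1")]
    if (min(gen) > max(spc)) ok <- ok + 1L
  }
  expect_gte(ok, n_seeds - 1L)
})
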