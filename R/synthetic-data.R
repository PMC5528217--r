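#' Simulate a pure-birth (Yule) host phylogeny
#'
#' Forward simulation: the root splits into two lineages at time zero and
#' each lineage thereafter splits at rate `birth_rate`; once the tree
#' reaches `n_tips` lineages one more exponential waiting time is drawn and
#' all pendant edges are extended to that horizon, so the tree is
#' ultrametric with strictly positive branch lengths and no root edge.
#' Tree depth is therefore a sum of independent exponentials with rates
#' `birth_rate * k`, `k = 2, ..., n_tips`, giving the closed-form mean
#' depth \eqn{\sum_{k=2}^{n} 1/(bk)} used as a Monte-Carlo oracle in the
#' package's tests (a single-tip tree is one pendant edge of length
#' `Exp(birth_rate)`).
#'
#' @param n_tips Number of tips (>= 1).
#' @param birth_rate Speciation rate per lineage.
#' @param seed Optional seed; `NULL` uses (and advances) the current RNG.
#' @return An ultrametric [ape::phylo] with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 1) abort("n_tips must be >= 1")
  stopifnot(birth_rate > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (n_tips == 1L) {
    len <- rexp(1, rate = birth_rate)
    return(ape::read.tree(text = paste0("(t1:",
                                        format(len, digits = 15), ");")))
  }
  # unit 1 is the root, splitting at time 0 into units 2 and 3
  t_birth <- c(0, 0, 0)
  children <- list(c(2L, 3L), integer(), integer())
  active <- c(2L, 3L)
  now <- 0
  k <- 2L
  while (k < n_tips) {
    now <- now + rexp(1, rate = birth_rate * k)
    u <- active[sample.int(length(active), 1L)]
    id1 <- length(t_birth) + 1L
    id2 <- id1 + 1L
    t_birth <- c(t_birth, now, now)
    children[[u]] <- c(id1, id2)
    children[[id1]] <- integer()
    children[[id2]] <- integer()
    active <- c(setdiff(active, u), id1, id2)
    k <- k + 1L
  }
  horizon <- now + rexp(1, rate = birth_rate * n_tips)
  tip_no <- 0L
  nwk <- function(u) {
    if (length(children[[u]]) == 0L) {
      tip_no <<- tip_no + 1L
      paste0("t", tip_no, ":", format(horizon - t_birth[u], digits = 15))
    } else {
      kids <- vapply(children[[u]], nwk, "")
      body <- paste0("(", paste(kids, collapse = ","), ")")
      if (u == 1L) body else
        paste0(body, ":",
               format(t_birth[children[[u]][1]] - t_birth[u], digits = 15))
    }
  }
  ape::read.tree(text = paste0(nwk(1L), ";"))
}

#' Configure a synthetic invasion scenario
#'
#' Defaults emulate the shape of the study system: 36 host plants in ~15
#' families on an ultrametric phylogeny; a fly community of three broad
#' generalists, three specialists confined to one clade ("cucurbit-like"),
#' one specialist confined to a second clade ("solanaceae-like"), and one
#' generalist invader that appears only after the invasion and shares hosts
#' with the resident generalists but with neither specialist clade.
#' Sampling depth per plant and period is heterogeneous (uniform on
#' `samples_per_plant`). After the invasion, resident generalist
#' preferences are contracted (see [make_niches()]); specialists are
#' unchanged.
#'
#' @param n_plants,n_families Host-assemblage size.
#' @param birth_rate Yule speciation rate for the host tree.
#' @param flies Tibble `fly_id, guild, clade` (`clade` one of `"none"`,
#'   `"cucurbit"`, `"solanaceae"`); guild `"invader"` marks the after-only
#'   species.
#' @param samples_per_plant Integer range (min, max) of fruit samples per
#'   plant per period.
#' @param contraction_factor In (0, 1]: after-period generalist preferences
#'   are the before preferences raised to `1/contraction_factor` and
#'   renormalised; values below 1 concentrate the diet.
#' @param count_model `"poisson"` or `"negbinom"`.
#' @param dispersion Negative-binomial size parameter (ignored for
#'   Poisson).
#' @param mean_load Expected flies per fruit on a fly's most preferred
#'   host.
#' @param generalist_hosts,invader_hosts Number of host plants in a
#'   generalist's / the invader's diet.
#' @param seed Scenario seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_plants = 36L, n_families = 15L,
                            birth_rate = 1,
                            flies = NULL,
                            samples_per_plant = c(6L, 25L),
                            contraction_factor = 0.5,
                            count_model = c("poisson", "negbinom"),
                            dispersion = 1, mean_load = 10,
                            generalist_hosts = 15L, invader_hosts = 8L,
                            seed = 1L) {
  count_model <- match.arg(count_model)
  if (is.null(flies)) {
    flies <- tibble::tibble(
      fly_id = c("gen1", "gen2", "gen3", "cuc1", "cuc2", "cuc3", "sol1",
                 "invader"),
      guild = c(rep("generalist", 3), rep("specialist", 4), "invader"),
      clade = c(rep("none", 3), rep("cucurbit", 3), "solanaceae", "none"))
  }
  stopifnot(n_plants >= 2, contraction_factor > 0, contraction_factor <= 1,
            length(samples_per_plant) == 2,
            samples_per_plant[1] >= 1,
            samples_per_plant[2] >= samples_per_plant[1])
  structure(list(n_plants = as.integer(n_plants),
                 n_families = as.integer(n_families),
                 birth_rate = birth_rate, flies = tibble::as_tibble(flies),
                 samples_per_plant = as.integer(samples_per_plant),
                 contraction_factor = contraction_factor,
                 count_model = count_model, dispersion = dispersion,
                 mean_load = mean_load,
                 generalist_hosts = as.integer(generalist_hosts),
                 invader_hosts = as.integer(invader_hosts),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# pick two disjoint clades of workable size; error if the tree offers none
pick_clades <- function(tree, target1 = 6L, target2 = 4L) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(i) labs[i])
  sizes <- lengths(sets)
  ntip <- ape::Ntip(tree)
  cand1 <- which(sizes >= 3 & sizes <= max(target1 + 4, 4) &
                   sizes < ntip)
  if (!length(cand1)) abort("no clade of usable size for the specialist guild")
  c1 <- cand1[which.min(abs(sizes[cand1] - target1))]
  disjoint <- vapply(sets, function(s) !any(s %in% sets[[c1]]), TRUE)
  cand2 <- which(disjoint & sizes >= 2 & sizes <= max(target2 + 4, 3))
  if (!length(cand2)) abort("no second disjoint clade for the specialist guild")
  c2 <- cand2[which.min(abs(sizes[cand2] - target2))]
  list(cucurbit = sets[[c1]], solanaceae = sets[[c2]])
}

# monophyletic-ish family labels from average-linkage cuts of the tip distances
assign_families <- function(tree, n_families) {
  n_families <- min(n_families, ape::Ntip(tree))
  if (ape::Ntip(tree) == 1L) {
    return(setNames("fam01", tree$tip.label))
  }
  hc <- stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)), "average")
  grp <- stats::cutree(hc, k = n_families)
  setNames(sprintf("fam%02d", grp), names(grp))
}

#' Build guild-structured niche profiles for both periods
#'
#' Specialist profiles are Dirichlet draws confined to their clade's tips
#' and identical in both periods. Generalist profiles are Dirichlet draws
#' over hosts outside the specialist clades, spanning at least three plant
#' families; after the invasion they are contracted by raising each
#' preference to `1/contraction_factor` and renormalising
#' (order-preserving; `contraction_factor = 1` leaves them unchanged). The
#' invader's profile covers a subset of the generalists' preferred hosts
#' (disjoint from both specialist clades) and exists only after the
#' invasion.
#'
#' @param tree Host phylogeny ([ape::phylo]).
#' @param scenario A [scenario_config()].
#' @return List with elements `before` and `after`: each a named list of
#'   niche profiles (`fly_id`, `preference` over all tips summing to 1,
#'   `mean_load`), plus `clades` and `families`.
#' @export
make_niches <- function(tree, scenario = scenario_config()) {
  tips <- tree$tip.label
  clades <- pick_clades(tree)
  for (cl in clades) if (length(cl) < 1) abort("specialist clade has no tips")
  families <- assign_families(tree, scenario$n_families)
  open_tips <- setdiff(tips, c(clades$cucurbit, clades$solanaceae))
  if (length(unique(families[open_tips])) < 3) {
    abort("fewer than three families available outside the specialist clades")
  }

  dirichlet <- function(support) {
    g <- stats::rgamma(length(support), shape = 1)
    g <- pmax(g, 1e-8)
    setNames(g / sum(g), support)
  }
  full <- function(pref) {
    out <- setNames(numeric(length(tips)), tips)
    out[names(pref)] <- pref
    out
  }

  gen_ids <- scenario$flies$fly_id[scenario$flies$guild == "generalist"]
  before <- list()
  top_hosts <- character()
  for (i in seq_len(nrow(scenario$flies))) {
    f <- scenario$flies[i, ]
    support <- switch(
      f$clade,
      cucurbit = clades$cucurbit,
      solanaceae = clades$solanaceae,
      none = {
        n_hosts <- if (f$guild == "invader") scenario$invader_hosts else
          scenario$generalist_hosts
        n_hosts <- min(n_hosts, length(open_tips))
        if (f$guild == "invader" && length(top_hosts)) {
          # overlap the resident generalists' favoured hosts
          pool <- unique(c(top_hosts, sample(open_tips)))
          head(pool, n_hosts)
        } else {
          sample(open_tips, n_hosts)
        }
      })
    pref <- dirichlet(support)
    if (f$guild == "generalist") {
      top_hosts <- unique(c(top_hosts,
                            names(sort(pref, decreasing = TRUE))[1:4]))
    }
    before[[f$fly_id]] <- list(fly_id = f$fly_id, guild = f$guild,
                               preference = full(pref),
                               mean_load = scenario$mean_load)
  }

  after <- before
  for (id in gen_ids) {
    p <- before[[id]]$preference
    q <- p^(1 / scenario$contraction_factor)
    after[[id]]$preference <- q / sum(q)
  }
  invader_ids <- scenario$flies$fly_id[scenario$flies$guild == "invader"]
  before[invader_ids] <- NULL

  list(before = before, after = after, clades = clades, families = families)
}

#' Simulate per-fruit emergence counts
#'
#' For every plant and period, a heterogeneous number of fruit samples is
#' drawn (uniform on `scenario$samples_per_plant`); within a fruit of plant
#' j, the count of fly i is Poisson (or negative-binomial) with mean
#' `mean_load_i * preference_ij / max_j(preference_ij)`, independent across
#' flies. Flies absent from a period's niche list (the invader before the
#' invasion) emerge nowhere in that period.
#'
#' @param niches Output of [make_niches()].
#' @param scenario A [scenario_config()].
#' @param invasion_year Invasion year stamped on the dataset.
#' @return A [fly_dataset()] with guild annotations and family labels.
#' @export
simulate_samples <- function(niches, scenario = scenario_config(),
                             invasion_year = 2000L) {
  tips <- names(niches$after[[1]]$preference)
  fly_ids <- scenario$flies$fly_id
  rows <- list()
  cnts <- list()
  for (period in c("before", "after")) {
    prof <- niches[[period]]
    rate <- matrix(0, length(tips), length(fly_ids),
                   dimnames = list(tips, fly_ids))
    for (id in names(prof)) {
      p <- prof[[id]]$preference
      rate[, id] <- prof[[id]]$mean_load * p / max(p)
    }
    depth_vals <- scenario$samples_per_plant[1]:scenario$samples_per_plant[2]
    n_per <- depth_vals[sample.int(length(depth_vals), length(tips),
                                   replace = TRUE)]
    plant_col <- rep(tips, n_per)
    n_fruit <- length(plant_col)
    mu <- rate[plant_col, , drop = FALSE]
    draw <- if (scenario$count_model == "poisson") {
      rpois(length(mu), lambda = as.vector(mu))
    } else {
      rnbinom(length(mu), mu = as.vector(mu), size = scenario$dispersion)
    }
    cm <- matrix(draw, n_fruit, length(fly_ids), dimnames = list(NULL, fly_ids))
    sid <- sprintf("%s_%s_%03d", period, plant_col,
                   sequence(n_per))
    rows[[period]] <- tibble::tibble(sample_id = sid, plant_id = plant_col,
                                     period = period)
    cnts[[period]] <- tibble::as_tibble(cbind(
      tibble::tibble(sample_id = sid), tibble::as_tibble(cm)))
  }
  plants <- tibble::tibble(plant_id = tips, name = tips,
                           family = unname(niches$families[tips]),
                           tree_tip_label = tips)
  flies <- tibble::tibble(fly_id = fly_ids, name = fly_ids,
                          guild = scenario$flies$guild)
  fly_dataset(dplyr::bind_rows(rows), dplyr::bind_rows(cnts),
              flies = flies, plants = plants, invasion_year = invasion_year)
}

#' Ground-truth indices of a niche architecture
#'
#' Niche breadth and pairwise turnover evaluated directly on the noiseless
#' preference profiles, for parameter-recovery tests.
#'
#' @param niches Output of [make_niches()] (or one period's profile list).
#' @return List of tibbles `alpha` (`fly_id, period, d_alpha`) and `pairs`
#'   (`fly_i, fly_k, period, turnover`).
#' @export
true_indices <- function(niches) {
  periods <- if (!is.null(niches$before) || !is.null(niches$after)) {
    list(before = niches$before, after = niches$after)
  } else {
    list(profile = niches)
  }
  alpha <- list()
  pairs <- list()
  for (pn in names(periods)) {
    prof <- periods[[pn]]
    if (is.null(prof)) next
    ids <- names(prof)
    alpha[[pn]] <- tibble::tibble(
      fly_id = ids, period = pn,
      d_alpha = unname(vapply(prof,
                              function(x) alpha_diversity(x$preference), 0)))
    if (length(ids) >= 2) {
      cmb <- utils::combn(ids, 2)
      pairs[[pn]] <- tibble::tibble(
        fly_i = cmb[1, ], fly_k = cmb[2, ], period = pn,
        turnover = apply(cmb, 2, function(ik) {
          beta_turnover(prof[[ik[1]]]$preference, prof[[ik[2]]]$preference)
        }))
    }
  }
  list(alpha = dplyr::bind_rows(alpha), pairs = dplyr::bind_rows(pairs))
}

#' Simulate a complete invasion study
#'
#' One call producing everything the pipeline consumes: a Yule host
#' phylogeny, guild-structured niche profiles for both periods, the
#' per-fruit dataset, and the ground-truth indices.
#'
#' @param scenario A [scenario_config()].
#' @param seed Seed for the whole simulation (defaults to the scenario's).
#' @return List `tree, niches, dataset, truth, scenario` (class
#'   `invasion_scenario`).
#' @export
simulate_invasion_scenario <- function(scenario = scenario_config(),
                                       seed = scenario$seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tree <- simulate_yule_tree(scenario$n_plants, scenario$birth_rate)
  niches <- make_niches(tree, scenario)
  dataset <- simulate_samples(niches, scenario)
  structure(list(tree = tree, niches = niches, dataset = dataset,
                 truth = true_indices(niches), scenario = scenario,
                 seed = seed),
            class = "invasion_scenario")
}
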