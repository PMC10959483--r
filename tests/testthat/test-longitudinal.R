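test_that("age bins are half-open with upward boundary assignment", {
  expect_equal(as.character(assign_age_bin(1.99)), "neonatal_infantile")
  expect_equal(as.character(assign_age_bin(2.0)), "childhood")
  expect_equal(as.character(assign_age_bin(12)), "juvenile")
  expect_equal(as.character(assign_age_bin(18.0)), "adult")
  expect_equal(as.character(assign_age_bin(25)), "adult")
  expect_error(assign_age_bin(-1), ">= 0")
  b <- age_bins()
  expect_equal(b$lo, c(0, 2, 12, 18))
  expect_true(all(b$hi[-4] == b$lo[-1]))  # partition of [0, Inf)
})

test_that("binned_scan restricts carriers to the bin and matches
           phenome_scan per bin", {
  persons <- tibble::tibble(
    person_id = sprintf("p%02d", 1:16),
    group = rep(c("case", "control"), each = 8))
  set.seed(5)
  ann <- tibble::tibble(
    person_id = sample(persons$person_id, 60, TRUE),
    term = sample(c("T:a", "T:b", "T:c"), 60, TRUE),
    age_years = runif(60, 0, 22))
  bs <- binned_scan(ann, persons, persons)
  for (b in unique(bs$bin)) {
    chunk <- ann[as.character(assign_age_bin(ann$age_years)) == b, ]
    ref <- phenome_scan(person_term_matrix(chunk, persons), persons)
    got <- dplyr::arrange(bs[bs$bin == b, names(ref)], p, term)
    expect_equal(tibble::as_tibble(got),
                 tibble::as_tibble(ref), ignore_attr = TRUE)
  }

  # a term observed only at age 5 counts in childhood only
  solo <- tibble::tibble(person_id = "p01", term = "T:solo", age_years = 5)
  bs2 <- binned_scan(dplyr::bind_rows(ann, solo), persons, persons)
  expect_equal(as.character(unique(bs2$bin[bs2$term == "T:solo"])),
               "childhood")
})

test_that("bin evidence covers the cross-sectional scan", {
  sim <- small_sim()
  ann <- sim_annotations(sim)
  pro <- propagate_annotations(ann, sim$ontology)
  cross <- phenome_scan(person_term_matrix(pro, sim$persons), sim$persons)
  bs <- binned_scan(pro, sim$persons, sim$persons)
  bin_carriers <- bs |>
    dplyr::group_by(term) |>
    dplyr::summarise(n = sum(a + c), .groups = "drop")
  both <- dplyr::inner_join(tibble::as_tibble(cross), bin_carriers,
                            by = "term")
  # summed bin carriers can only exceed cross-sectional carriers
  expect_true(all(both$n >= both$a + both$c))
})

test_that("trajectory clustering is deterministic and Ward heights match
           the Lance-Williams oracle", {
  tm <- rbind(
    a = c(2, 2, 1.8, 2.1),
    b = c(2, 2.1, 1.9, 2),
    c = c(-1, -1.2, -0.8, -1),
    d = c(-1.1, -1, -0.9, -1.05))
  colnames(tm) <- as.character(age_bins()$bin)
  cl <- cluster_trajectories(tm, k = 2)
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_equal(cl$clusters[["c"]], cl$clusters[["d"]])
  expect_false(cl$clusters[["a"]] == cl$clusters[["c"]])
  expect_equal(sort(cl$hclust$height), sort(oracle_ward_heights(tm)),
               tolerance = 1e-8)

  # identical rows always co-cluster
  tm2 <- rbind(x = c(1, 0, 0, 0), y = c(1, 0, 0, 0), z = c(0, 5, 0, 0))
  cl2 <- cluster_trajectories(tm2, k = 2)
  expect_equal(cl2$clusters[["x"]], cl2$clusters[["y"]])

  # all-missing rows are excluded with a warning
  tm3 <- rbind(x = c(1, NA, NA, NA), y = c(NA_real_, NA, NA, NA),
               z = c(0, 1, 0, 0))
  expect_warning(cl3 <- cluster_trajectories(tm3, k = 2), "excluded")
  expect_false("y" %in% names(cl3$clusters))
})

test_that("utilization metrics agree with independent group tallies", {
  persons <- tibble::tibble(
    person_id = c("a", "b", "c", "d", "e", "f"),
    group = c("case", "case", "control", "control", "case", "control"))
  enc <- tibble::tibble(
    person_id = c("a", "a", "b", "c", "d", "d", "e", "f"),
    age_years = c(1.2, 2.5, 3, 1, 2, 19, 4, 6),
    setting = c("outpatient", "emergency", "outpatient", "outpatient",
                "emergency", "outpatient", "emergency", "emergency"),
    cost = c(100, 500, 120, 90, 480, 110, 470, 460))
  ann <- tibble::tibble(
    person_id = c("a", "a", "a", "a", "b"),
    age_years = c(1.2, 1.2, 1.2, 2.5, 3))
  um <- utilization_metrics(persons, enc, ann)
  # person a: encounters at 1.2 (3 concepts) and 2.5 (1 concept) -> mean 2
  expect_equal(
    um$per_person$concepts_per_encounter[um$per_person$person_id == "a"], 2)
  expect_equal(
    um$per_person$n_emergency[um$per_person$person_id == "d"], 1)
  # annual counts: person a has 1 encounter in year 1 and 1 in year 2
  aa <- um$annual[um$annual$person_id == "a", ]
  expect_equal(sort(aa$age_year), c(1, 2))
  expect_equal(aa$n_encounters, c(1, 1))
  # ED contrast conditions on >= 1 admission: persons a, e vs d, f
  expect_true("emergency_admissions" %in% um$contrasts$metric)
  ed <- um$contrasts[um$contrasts$metric == "emergency_admissions", ]
  expect_equal(ed$mean_x, 1)
  expect_equal(ed$mean_y, 1)
})

test_that("transition_window finds a planted bump and scales
           equivariantly", {
  flat <- tidyr::expand_grid(
    group = c("case", "control"),
    tibble::tibble(lo = 0, hi = Inf, rate = 3.6))
  cfg <- sim_config(n_cases = 150, n_controls = 150, seed = 31,
                    n_terms = 10, n_filler = 4, encounter_rates = flat,
                    transition_bump = 1.7, bump_ages = c(18, 20),
                    followup = list(full = TRUE), catalogue = NULL,
                    concept_mu = c(case = 1, control = 1))
  sim <- simulate_cohort(cfg)
  tw <- transition_window(sim$persons, sim$encounters)
  expect_equal(c(tw$best$lo, tw$best$hi), c(18, 20))
  expect_lt(tw$best$p, 0.01)
  expect_gt(tw$best$ratio, 1.3)

  # doubling case encounters doubles every ratio
  dbl <- dplyr::bind_rows(
    sim$encounters,
    dplyr::semi_join(sim$encounters,
                     dplyr::filter(sim$persons, group == "case"),
                     by = "person_id"))
  tw2 <- transition_window(sim$persons, dbl)
  expect_equal(tw2$windows$ratio, tw$windows$ratio * 2, tolerance = 1e-9)
})

test_that("window enrichment builds the in-window versus pre-window
           tables it claims", {
  persons <- tibble::tibble(person_id = c("a", "b", "c", "d"),
                            group = c("case", "case", "case", "case"))
  ann <- tibble::tibble(
    person_id = c("a", "a", "b", "b", "c", "d", "d"),
    term = c("T:pre", "T:in", "T:in", "T:pre", "T:pre", "T:pre", "T:both"),
    age_years = c(10, 19, 18.5, 11, 10, 12, 19))
  # everyone observed before and into the window
  fu <- tibble::tibble(person_id = c("a", "b", "c", "d"),
                       first_age = 9, last_age = 20)
  we <- window_concept_enrichment(ann, persons, window = c(18, 20),
                                  followup = fu, top_k = Inf)
  row_in <- we[we$term == "T:in", ]
  expect_equal(row_in$in_window, 2)
  expect_equal(row_in$pre_window, 0)
  expect_equal(row_in$or, Inf)
  direct <- fisher_exact(2, 2, 0, 4)
  expect_equal(row_in$p, direct$p)
  row_pre <- we[we$term == "T:pre", ]
  expect_equal(row_pre$in_window, 0)
  expect_equal(row_pre$pre_window, 4)
})

test_that("a childhood-restricted planted effect is recovered in its bin
           and absent elsewhere", {
  g <- simulate_ontology(30, 6, seed = 61)
  leaf <- attr(g, "roles")$term[attr(g, "roles")$role == "leaf"][1]
  cfg <- sim_config(
    n_cases = 1000, n_controls = 1000, seed = 62, ontology = g,
    baseline_prevalence = 0.2, catalogue = NULL,
    followup = list(full = TRUE),
    concept_mu = c(case = 2, control = 2),
    encounter_rates = tidyr::expand_grid(
      group = c("case", "control"),
      tibble::tibble(lo = 0, hi = Inf, rate = 1)),
    transition_bump = 1,
    planted_effects = tibble::tibble(term = leaf, or = 3,
                                     bin = "childhood"))
  sim <- simulate_cohort(cfg)
  ann_all <- sim_annotations(sim)
  bs <- binned_scan(ann_all, sim$persons, sim$persons)
  target <- bs[bs$term == leaf, ]
  child <- target[target$bin == "childhood", ]
  expect_lt(child$p_adj, 0.05)
  expect_gt(child$or, 2)
  other <- target[target$bin != "childhood", ]
  # the effect is expressed only inside its bin: elsewhere the term is
  # rare (forced observations stay in childhood) and never significant
  expect_true(all(other$p_adj > 0.05 | nrow(other) == 0))
})
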