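rx_row <- function(id, drug, age = 1, class = "sodium_channel",
                   asm = TRUE) {
  tibble::tibble(person_id = id, age_years = age, drug = drug,
                 drug_class = class, is_asm = asm)
}

test_that("the 1% prevalence filter uses a ceiling on distinct persons", {
  mk <- function(n_persons) {
    dplyr::bind_rows(lapply(seq_len(n_persons), function(i) {
      rx_row(sprintf("p%03d", i), "drugA")
    }))
  }
  # cohort 503: ceiling(0.01 * 503) = 6 exposed persons required
  expect_equal(filter_asm_by_prevalence(mk(5), 503), character(0))
  expect_equal(filter_asm_by_prevalence(mk(6), 503), "drugA")
  # boundary: exactly 1% of 100
  expect_equal(filter_asm_by_prevalence(mk(1), 100), "drugA")
  # repeat prescriptions to one person do not help
  rep5 <- dplyr::bind_rows(replicate(10, rx_row("p1", "drugB"),
                                     simplify = FALSE))
  expect_equal(filter_asm_by_prevalence(rep5, 503), character(0))
  # monotone in threshold
  expect_true(all(filter_asm_by_prevalence(mk(6), 503, 0.012) %in%
                    filter_asm_by_prevalence(mk(6), 503, 0.01)))
})

test_that("unique ASM counts are set cardinalities per person", {
  persons <- tibble::tibble(person_id = c("p1", "p2", "p3"),
                            group = c("case", "case", "control"))
  rx <- dplyr::bind_rows(
    rx_row("p1", "levetiracetam"), rx_row("p1", "levetiracetam"),
    rx_row("p1", "valproic acid"),
    rx_row("p3", "levetiracetam"),
    rx_row("p2", "aspirin", asm = FALSE))
  out <- unique_asm_count(rx, persons)
  expect_equal(out$per_person$n_unique_asm,
               c(2, 0, 1)[match(out$per_person$person_id,
                                c("p1", "p2", "p3"))])
  # independent set-cardinality oracle
  oracle <- rx |>
    dplyr::filter(is_asm) |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(n = dplyr::n_distinct(drug))
  for (i in seq_len(nrow(oracle))) {
    expect_equal(
      out$per_person$n_unique_asm[out$per_person$person_id ==
                                    oracle$person_id[i]],
      oracle$n[i])
  }
})

test_that("rescue counts are event tallies in the benzodiazepine class", {
  persons <- tibble::tibble(person_id = c("p1", "p2"),
                            group = c("case", "control"))
  rx <- dplyr::bind_rows(
    rx_row("p1", "diazepam", class = "benzodiazepine"),
    rx_row("p1", "diazepam", class = "benzodiazepine"),
    rx_row("p1", "diazepam", class = "benzodiazepine"),
    rx_row("p1", "levetiracetam", class = "sv2a"),
    rx_row("p2", "lorazepam", class = "benzodiazepine"))
  out <- rescue_prescription_count(rx, persons)
  expect_equal(out$per_person$n_rescue[out$per_person$person_id == "p1"], 3)
  expect_equal(out$per_person$n_rescue[out$per_person$person_id == "p2"], 1)
})

test_that("binned prescription scan matches direct Fisher tables", {
  persons <- tibble::tibble(
    person_id = sprintf("p%02d", 1:20),
    group = rep(c("case", "control"), each = 10))
  # drugX given to 6 cases in infancy only; drugY given to everyone
  rx <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(sprintf("p%02d", 1:6), function(i) {
      rx_row(i, "drugX", age = 1)
    })),
    dplyr::bind_rows(lapply(persons$person_id, function(i) {
      rx_row(i, "drugY", age = 5, class = "sv2a")
    })))
  scan <- binned_prescription_scan(rx, persons, threshold = 0.01)
  x_inf <- scan[scan$drug == "drugX" &
                  scan$bin == "neonatal_infantile", ]
  expect_equal(c(x_inf$a, x_inf$b, x_inf$c, x_inf$d), c(6, 4, 0, 10))
  direct <- fisher_exact(6, 4, 0, 10)
  expect_equal(x_inf$or, Inf)
  expect_equal(x_inf$p, direct$p)
  # identical exposure: no signal
  y_child <- scan[scan$drug == "drugY" & scan$bin == "childhood", ]
  expect_equal(y_child$p, 1)
  # Bonferroni is per bin over drugs tested in the bin
  infancy <- scan[scan$bin == "neonatal_infantile", ]
  expect_equal(infancy$p_adj,
               pmin(1, infancy$p * nrow(infancy)))
})

test_that("simulated prescriptions recover group medication burden", {
  sim <- small_sim()
  ua <- unique_asm_count(sim$prescriptions, sim$persons)
  expect_gt(ua$contrast$mean_x, ua$contrast$mean_y)
  rc <- rescue_prescription_count(sim$prescriptions, sim$persons)
  expect_gt(rc$contrast$mean_x, 0)
})

test_that("a planted early-levetiracetam excess in cases lights up the
           early bins only", {
  set.seed(77)
  n <- 150
  persons <- tibble::tibble(
    person_id = sprintf("p%03d", 1:(2 * n)),
    group = rep(c("case", "control"), each = n))
  cases <- persons$person_id[persons$group == "case"]
  controls <- persons$person_id[persons$group == "control"]
  rx <- dplyr::bind_rows(
    # infancy exposure: 60 cases vs 10 controls
    tibble::tibble(person_id = c(sample(cases, 60), sample(controls, 10)),
                   age_years = runif(70, 0, 2),
                   drug = "levetiracetam", drug_class = "sv2a",
                   is_asm = TRUE),
    # adult exposure: balanced
    tibble::tibble(person_id = c(sample(cases, 30), sample(controls, 30)),
                   age_years = runif(60, 18, 22),
                   drug = "levetiracetam", drug_class = "sv2a",
                   is_asm = TRUE),
    # a balanced comparator drug across all ages
    tibble::tibble(person_id = c(sample(cases, 40), sample(controls, 40)),
                   age_years = runif(80, 0, 22),
                   drug = "valproic acid", drug_class = "broad_spectrum",
                   is_asm = TRUE))
  scan <- binned_prescription_scan(rx, persons)
  lev_inf <- scan[scan$drug == "levetiracetam" &
                    scan$bin == "neonatal_infantile", ]
  expect_lt(lev_inf$p_adj, 0.05)
  expect_gt(lev_inf$or, 2)
  lev_adult <- scan[scan$drug == "levetiracetam" & scan$bin == "adult", ]
  expect_gt(lev_adult$p_adj, 0.05)
})
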