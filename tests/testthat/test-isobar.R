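# Isobar grouping, cross-mix RT anchoring and exclusion filtering.

mk_peaks <- function(rts, ints = NULL) {
  ints <- ints %||% rep(1e6, length(rts))
  tibble::tibble(rt_apex = rts, intensity_apex = ints, snr = 10,
                 rt_left = rts - 0.2, rt_right = rts + 0.2)
}

fig4_tables <- function() {
  compounds <- tibble::tibble(
    id = c("amine", "acetamide"),
    mass = rep(monoisotopic_mass("C10H13NO"), 2))
  design <- tibble::tibble(id = c("amine", "amine", "acetamide"),
                           mix = c("503", "508", "508"))
  det <- tibble::tibble(
    id = c("amine", "amine", "acetamide"),
    mix = c("503", "508", "508"),
    peaks = list(mk_peaks(12.3, 2e6),
                 mk_peaks(c(12.3, 14.4), c(2e6, 3e6)),
                 mk_peaks(c(12.3, 14.4), c(2e6, 3e6))))
  list(compounds = compounds, design = design, det = det)
}

test_that("grouping follows the 1 Da isolation window with transitivity", {
  fx <- fig4_tables()
  g <- group_isobars(fx$design, fx$compounds)
  g508 <- g[g$mix == "508", ]
  expect_equal(unique(g508$group), unique(g508$group)[1])
  expect_equal(g508$n_members, c(2L, 2L))

  far <- tibble::tibble(id = c("a", "b"), mass = c(100, 110))
  g2 <- group_isobars(tibble::tibble(id = c("a", "b"), mix = "m"), far)
  expect_equal(dplyr::n_distinct(g2$group), 2)

  # transitive chaining: 0.6 Da gaps merge three compounds into one group
  chain <- tibble::tibble(id = c("a", "b", "c"), mass = c(100, 100.6, 101.2))
  g3 <- group_isobars(tibble::tibble(id = c("a", "b", "c"), mix = "m"), chain)
  expect_equal(dplyr::n_distinct(g3$group), 1)

  empty <- group_isobars(tibble::tibble(id = character(), mix = character()),
                         far)
  expect_equal(nrow(empty), 0)
})

test_that("the two-mix worked example resolves by elimination", {
  fx <- fig4_tables()
  g <- group_isobars(fx$design, fx$compounds)
  a <- resolve_isobars(g, fx$det)
  amine503 <- a[a$id == "amine" & a$mix == "503", ]
  expect_equal(amine503$level, "1")
  expect_equal(amine503$rt, 12.3)
  acet <- a[a$id == "acetamide" & a$mix == "508", ]
  expect_equal(acet$level, "1")
  expect_equal(acet$rationale, "by_elimination")
  expect_equal(acet$rt, 14.4)
})

test_that("isobars that always co-occur stay at level 3", {
  fx <- fig4_tables()
  design <- fx$design[fx$design$mix == "508", ]
  det <- fx$det[fx$det$mix == "508", ]
  a <- resolve_isobars(group_isobars(design, fx$compounds), det)
  expect_true(all(a$level == "3"))
  expect_true(all(a$rationale == "ambiguous"))
})

test_that("groups without peaks are reported as not detected", {
  fx <- fig4_tables()
  det <- fx$det
  det$peaks <- list(mk_peaks(numeric()), mk_peaks(numeric()), mk_peaks(numeric()))
  a <- resolve_isobars(group_isobars(fx$design, fx$compounds), det)
  expect_true(all(a$level == "not_detected"))
  expect_true(all(a$rationale == "no_peak"))
})

test_that("co-eluting anchored isobars are demoted to level 3", {
  compounds <- tibble::tibble(id = c("p", "q"),
                              mass = rep(monoisotopic_mass("C10H13NO"), 2))
  # both compounds anchored in solo mixes at the SAME retention time
  design <- tibble::tibble(id = c("p", "q", "p", "q"),
                           mix = c("m1", "m2", "m3", "m3"))
  det <- tibble::tibble(
    id = c("p", "q", "p", "q"),
    mix = c("m1", "m2", "m3", "m3"),
    peaks = list(mk_peaks(8.0), mk_peaks(8.1),
                 mk_peaks(8.05), mk_peaks(8.05)))
  a <- resolve_isobars(group_isobars(design, compounds), det)
  m3 <- a[a$mix == "m3", ]
  expect_true(all(m3$level == "3"))
})

test_that("resolution is deterministic under input reordering", {
  fx <- fig4_tables()
  g <- group_isobars(fx$design, fx$compounds)
  a1 <- resolve_isobars(g, fx$det)
  perm <- c(3, 1, 2)
  a2 <- resolve_isobars(g[order(-seq_len(nrow(g))), ], fx$det[perm, ])
  expect_equal(a1, a2)
})

test_that("well-separated anchored designs are recovered without error", {
  # property over generated designs: separated RTs + a disambiguating mix
  for (seed in c(2, 9)) {
    d <- generate_design(sizes = c(10, 10), mix_names = c("A", "B"),
                         isobar_plan = 2, seed = seed)
    truth <- d$compounds
    det <- d$design |>
      dplyr::inner_join(truth, by = "id") |>
      dplyr::mutate(peaks = purrr::map(rt, mk_peaks)) |>
      dplyr::select(id, mix, peaks)
    # members of one isobar group see the union of the group's peaks
    g <- group_isobars(d$design, truth)
    multi <- g |> dplyr::filter(n_members > 1)
    for (i in seq_len(nrow(multi))) {
      mates <- g$id[g$mix == multi$mix[[i]] & g$group == multi$group[[i]]]
      rts <- sort(truth$rt[truth$id %in% mates])
      det$peaks[det$id == multi$id[[i]] & det$mix == multi$mix[[i]]] <-
        list(mk_peaks(rts))
    }
    a <- resolve_isobars(g, det)
    a1 <- a[a$level == "1", ]
    expect_equal(nrow(a1), nrow(a))       # everything resolvable
    expect_equal(a1$rt, truth$rt[match(a1$id, truth$id)], tolerance = 1e-9)
    # conservativeness: no two level-1 assignments share a peak in a mix-group
    joined <- a1 |> dplyr::inner_join(g, by = c("id", "mix"))
    clash <- joined |>
      dplyr::group_by(mix, group, rt) |>
      dplyr::filter(dplyr::n() > 1)
    expect_equal(nrow(clash), 0)
  }
})

test_that("filter_records keeps level-1 spectra and logs the rest", {
  spectra <- tibble::tibble(id = c("a", "b", "c"), mix = "m",
                            spec = as.list(1:3))
  asg <- tibble::tibble(id = c("a", "b", "c"), mix = "m",
                        level = c("1", "1", "3"),
                        rationale = c("alone_in_mix", "by_elimination", "ambiguous"))
  out <- filter_records(spectra, asg)
  expect_equal(out$retained$id, c("a", "b"))
  expect_equal(out$excluded$id, "c")
  expect_equal(out$excluded$rationale, "ambiguous")

  all3 <- asg; all3$level <- "3"
  out2 <- filter_records(spectra, all3)
  expect_equal(nrow(out2$retained), 0)
  expect_equal(nrow(out2$excluded), 3)
})
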