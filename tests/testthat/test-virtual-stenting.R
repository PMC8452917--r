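test_that("stenting a healthy segment at the local diameter is the identity", {
  tr <- make_tube(L = 40, r = 1.5)
  st <- stent_spec("tube", 10, 36, diameter = 3)
  out <- deploy_stent(tr, st)
  expect_lt(max(abs(out$branches$tube$samples$r - 1.5)) / 1.5, 0.01)
})

test_that("interior sections sit every 3 mm strictly inside the span", {
  tr <- make_tube(L = 60, r = 2, spacing = 0.1)
  # a 26 mm stent carries 8 interior sections (3..24 mm past P*)
  st <- stent_spec("tube", 10, 36, diameter = 3)
  out <- deploy_stent(tr, st)
  r_out <- function(tree, s) stats::approx(tree$branches$tube$samples$s,
                                           tree$branches$tube$samples$r,
                                           xout = s)$y
  for (k in 1:8) expect_equal(r_out(out, 10 + 3 * k), 1.5, tolerance = 1e-6)
  # span ends keep the original lumen radius
  expect_equal(r_out(out, 10), 2, tolerance = 1e-6)
  expect_equal(r_out(out, 36), 2, tolerance = 1e-6)
  # a span that is an exact multiple of the spacing excludes the tie at D*
  st24 <- stent_spec("tube", 10, 34, diameter = 3)
  out24 <- deploy_stent(tr, st24)
  expect_equal(r_out(out24, 34), 2, tolerance = 1e-6)
  expect_equal(r_out(out24, 31), 1.5, tolerance = 1e-6)
})

test_that("stenting a deep lesion restores at least 95% of the stent diameter", {
  tr <- make_tube(L = 50, r = 1.5, spacing = 0.25)
  dis <- apply_stenosis(tr, stenosis_spec("tube", 25, 14, 80))
  st <- stent_spec("tube", 18, 32, diameter = 3)
  out <- deploy_stent(dis, st)
  sm <- out$branches$tube$samples
  span <- sm$s >= 18 & sm$s <= 32
  expect_gte(min(2 * sm$r[span]), 0.95 * 3)
  # untouched outside the span, input not mutated
  expect_identical(sm$r[!span], dis$branches$tube$samples$r[!span])
  expect_equal(min(dis$branches$tube$samples$r), 1.5 * 0.2, tolerance = 1e-9)
})

test_that("stent spans outside the branch raise geometry errors", {
  tr <- make_tube(L = 30, r = 1.5)
  expect_error(deploy_stent(tr, stent_spec("tube", 20, 40, 3)),
               class = "coroflow_geometry_error")
  expect_error(stent_spec("tube", 20, 10, 3),
               class = "coroflow_geometry_error")
})

test_that("auto-sizing recovers a cosine lesion's extent and reference diameter", {
  # 50 %DS dip centered at s = 16 spanning [10, 22] in a uniform 3 mm vessel
  tr <- make_tube(L = 32, r = 1.5, spacing = 0.5)
  dis <- apply_stenosis(tr, stenosis_spec("tube", 16, 12, 50))
  st <- auto_size_stent(dis, "tube")
  expect_equal(st$length, 12, tolerance = 0.5)
  expect_equal(st$diameter, 3, tolerance = 0.02 * 3)
  expect_equal(st$s_proximal, 10, tolerance = 0.5)
  expect_equal(st$s_distal, 22, tolerance = 0.5)
})

test_that("auto-sizing fails informatively on a lesion-free vessel", {
  expect_error(auto_size_stent(make_tube(L = 30, r = 1.5), "tube"),
               class = "coroflow_no_lesion_error")
})

test_that("with two lesions the sizer brackets only the deeper one", {
  tr <- make_tube(L = 80, r = 1.5, spacing = 0.25)
  dis <- apply_stenosis(tr, stenosis_spec("tube", 20, 10, 40))
  dis <- apply_stenosis(dis, stenosis_spec("tube", 55, 10, 70))
  st <- auto_size_stent(dis, "tube")
  expect_gt(st$s_proximal, 45)
  expect_lt(st$s_distal, 65)
})

test_that("auto-sizing recovers constructed stenoses across severities and seeds", {
  for (sev in c(35, 55, 75)) {
    for (seed in c(6, 14)) {
      cs <- make_stenosed_case(seed, severity = sev)
      st <- auto_size_stent(cs$diseased, cs$branch_id)
      spacing <- mean(diff(cs$diseased$branches[[cs$branch_id]]$samples$s))
      expect_lt(abs(st$length - cs$stenosis$length), spacing + 1e-9)
      expect_lt(abs(st$diameter - cs$ref_d) / cs$ref_d, 0.02)
    }
  }
})

test_that("lesion classes follow the clinical definitions with precedence", {
  # parent with a daughter taking off mid-vessel
  sr <- seq(0, 40, 0.5); sc <- seq(0, 20, 0.5)
  tr <- coronary_tree(list(
    branch("lad", s = sr, r = rep(1.8, length(sr))),
    branch("d1", s = sc, r = rep(1.2, length(sc)),
           parent_id = "lad", attach_s = 20)))
  mk <- function(bid, lo, hi, ds) lesion_record(bid, c(lo, hi), 1, 3, ds)
  # isolated mid-vessel lesion: focal
  out <- classify_lesions(tr, list(mk("lad", 8, 14, 60)))
  expect_identical(out[[1]]$type, "focal")
  # spans the daughter take-off: bifurcation
  out <- classify_lesions(tr, list(mk("lad", 17, 23, 60)))
  expect_identical(out[[1]]$type, "bifurcation")
  # within 3 mm of the vessel origin: ostial, beating bifurcation
  out <- classify_lesions(tr, list(mk("d1", 1, 5, 60)))
  expect_identical(out[[1]]$type, "ostial")
  # two >= 50 %DS lesions on one path: tandem members
  out <- classify_lesions(tr, list(mk("lad", 8, 12, 55),
                                   mk("lad", 28, 33, 55)))
  expect_identical(vapply(out, function(x) x$type, character(1)),
                   c("tandem-member", "tandem-member"))
  # tandem across a parent-child path
  out <- classify_lesions(tr, list(mk("lad", 8, 12, 55),
                                   mk("d1", 8, 12, 55)))
  expect_identical(vapply(out, function(x) x$type, character(1)),
                   c("tandem-member", "tandem-member"))
  # a sub-50 %DS companion does not create a tandem pair
  out <- classify_lesions(tr, list(mk("lad", 8, 12, 55),
                                   mk("lad", 28, 33, 45)))
  expect_identical(vapply(out, function(x) x$type, character(1)),
                   c("focal", "focal"))
  expect_error(classify_lesions(tr, list(mk("nope", 1, 2, 60))),
               class = "coroflow_lookup_error")
})
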