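test_that("a minimal single-branch JSON file parses to one branch, one outlet", {
  f <- tempfile(fileext = ".json")
  writeLines('
  {"root_id": "b1",
   "branches": [{"id": "b1", "parent_id": null, "attach_s": null,
                 "label": "LAD",
                 "samples": [{"s": 0, "r": 2, "xyz": null},
                             {"s": 10, "r": 1.9, "xyz": null},
                             {"s": 20, "r": 1.8, "xyz": null}]}],
   "metadata": {}}', f)
  tr <- read_tree(f)
  expect_length(tr$branches, 1L)
  expect_identical(outlet_ids(tr), "b1")
  expect_identical(tr$branches$b1$label, "LAD")
})

test_that("JSON and CSV round-trips preserve randomized trees", {
  for (seed in c(2, 11, 29)) {
    tr <- generate_tree(seed = seed, generations = 2)
    fj <- tempfile(fileext = ".json")
    write_tree(tr, fj)
    tr_j <- read_tree(fj)
    expect_equal(tr_j$branches, tr$branches, tolerance = 1e-9)
    expect_identical(tr_j$root_id, tr$root_id)
    fc <- tempfile(fileext = ".csv")
    write_tree(tr, fc)
    tr_c <- read_tree(fc)
    expect_equal(lapply(tr_c$branches, `[`, c("samples", "parent_id", "attach_s")),
                 lapply(tr$branches, `[`, c("samples", "parent_id", "attach_s")),
                 tolerance = 1e-9)
  }
})

test_that("malformed inputs raise parse or topology errors naming the problem", {
  f <- tempfile(fileext = ".json")
  writeLines('{"root_id": "a", "branches": [
    {"id": "a", "parent_id": null, "samples": [{"s":0,"r":1},{"s":5,"r":1}]},
    {"id": "b", "parent_id": "ghost", "attach_s": 2,
     "samples": [{"s":0,"r":0.9},{"s":5,"r":0.9}]}]}', f)
  expect_error(read_tree(f), class = "coroflow_topology_error")
  expect_error(read_tree(f), "ghost")
  writeLines("this is not json", f)
  expect_error(read_tree(f), class = "coroflow_parse_error")
  expect_error(read_tree(tempfile()), class = "coroflow_parse_error")
})

test_that("tree validation rejects invariant-breaking corruptions", {
  base <- function() list(
    branch("p", s = seq(0, 10, 1), r = rep(2, 11)),
    branch("c", s = seq(0, 8, 1), r = rep(1.5, 9),
           parent_id = "p", attach_s = 10))
  expect_s3_class(coronary_tree(base()), "coronary_tree")
  # negative radius
  brs <- base(); brs[[1]]$samples$r[3] <- -1
  expect_error(coronary_tree(brs), class = "coroflow_topology_error")
  # non-monotone arc length
  brs <- base(); brs[[2]]$samples$s[4] <- 1
  expect_error(coronary_tree(brs), class = "coroflow_topology_error")
  # attach beyond the parent
  brs <- base(); brs[[2]]$attach_s <- 99
  expect_error(coronary_tree(brs), class = "coroflow_topology_error")
  # two roots
  brs <- base(); brs[[2]]$parent_id <- NA_character_
  expect_error(coronary_tree(brs), class = "coroflow_topology_error")
  # cycle
  brs <- base(); brs[[1]]$parent_id <- "c"; brs[[1]]$attach_s <- 1
  expect_error(coronary_tree(brs), class = "coroflow_topology_error")
  # single sample
  expect_error(coronary_tree(list(branch("p", s = 0, r = 2))),
               class = "coroflow_topology_error")
  # empty tree
  expect_error(coronary_tree(list()), class = "coroflow_topology_error")
})

test_that("sub-resolution radii warn but do not fail", {
  s <- seq(0, 10, 1)
  expect_warning(coronary_tree(list(branch("t", s = s, r = rep(0.5, 11)))),
                 "below")
})

test_that("the lumen-area curve is pi r^2 on the branch grid", {
  tr <- make_tube(L = 30, r = 1.5)
  ac <- lumen_area_curve(tr, "tube")
  expect_equal(ac$area, rep(pi * 1.5^2, nrow(ac)), tolerance = 1e-12)
  expect_equal(ac$area[1], 7.0686, tolerance = 1e-4)
  ac2 <- lumen_area_curve(suppressWarnings(make_tube(r = 0.5, spacing = 5)),
                          "tube")
  expect_equal(ac2$area[1], 0.7854, tolerance = 1e-4)
  # monotone radius gives monotone area; pointwise consistency to 1e-9
  s <- seq(0, 20, 0.5)
  r <- seq(2, 1, length.out = length(s))
  tr3 <- coronary_tree(list(branch("t", s = s, r = r)))
  ac3 <- lumen_area_curve(tr3, "t")
  expect_true(all(diff(ac3$area) < 0))
  expect_equal(ac3$area, pi * r^2, tolerance = 1e-9)
  expect_error(lumen_area_curve(tr, "nope"), class = "coroflow_lookup_error")
})

test_that("VTK export writes one polyline per branch", {
  tr <- make_fork()
  fv <- tempfile(fileext = ".vtk")
  write_tree(tr, fv)
  txt <- readLines(fv)
  ln <- txt[grepl("^LINES", txt)]
  expect_length(ln, 1L)
  expect_match(ln, "^LINES 3 ")   # root + two daughters
  expect_true(any(grepl("^SCALARS radius", txt)))
})
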