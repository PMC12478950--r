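test_that("osim files round-trip to an identical model", {
  dir <- withr::local_tempdir()
  write_model(fix_unilateral, file.path(dir, "uni.osim"))
  m1 <- read_model(file.path(dir, "uni.osim"))
  expect_length(m1$bodies, 3)
  expect_length(m1$muscles, 14)
  expect_length(unlist(lapply(m1$joints, function(j) j$coordinates),
                       recursive = FALSE), 6)
  # read -> write -> read is the identity
  write_model(m1, file.path(dir, "uni2.osim"))
  m2 <- read_model(file.path(dir, "uni2.osim"))
  expect_equal(m2, m1, tolerance = 1e-12)
  # and the parse agrees with the in-memory source, field by field
  expect_equal(m1[-1], fix_unilateral[-1], tolerance = 1e-12)
})

test_that("unsupported model elements survive as opaque pass-through", {
  dir <- withr::local_tempdir()
  m <- fix_unilateral
  m$extra <- "<MarkerSet><objects/></MarkerSet>"
  f <- file.path(dir, "extra.osim")
  write_model(m, f)
  m2 <- read_model(f)
  expect_match(m2$extra, "MarkerSet")
  write_model(m2, f)
  expect_match(paste(readLines(f), collapse = ""), "<MarkerSet>")
})

test_that("a zero-mass body writes and re-reads as zero", {
  dir <- withr::local_tempdir()
  m <- make_shared_load(fix_bilateral, weight = 0)
  f <- file.path(dir, "zero.osim")
  write_model(m, f)
  expect_identical(read_model(f)$bodies$shared_load$mass, 0)
})

test_that("the bilateral model writes 28 muscle elements", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bi.osim")
  write_model(fix_bilateral, f)
  # independent check: raw text scan, not the parser
  expect_length(grep("<Thelen2003Muscle ", readLines(f)), 28)
})

test_that("dangling cross-references are rejected, one at a time", {
  corrupt <- list(
    function(m) { m$joints$shoulder_r$parent <- "thoraxX"; m },
    function(m) { m$joints$elbow_r$child <- "humerusX"; m },
    function(m) { m$muscles[[1]]$path[[1]]$body <- "scapulaX"; m },
    function(m) {
      m$constraints <- list(constraint_def("c", "shared_loadX", "hand"))
      m
    })
  for (f in corrupt) {
    bad <- f(fix_unilateral)
    expect_error(validate_model(bad), "X")
    expect_error(write_model(bad, tempfile(fileext = ".osim")), "X")
  }
  # a file whose joint cites an absent body fails on read too
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.osim")
  write_model(fix_unilateral, path)
  txt <- gsub("<parent_body>humerus_r</parent_body>",
              "<parent_body>humerusX</parent_body>", readLines(path))
  writeLines(txt, path)
  expect_error(read_model(path), "humerusX")
})

test_that("malformed XML raises a parse error", {
  f <- tempfile(fileext = ".osim")
  writeLines(c("<OpenSimDocument>", "<Model name='m'>"), f)
  expect_error(read_model(f), "parse error")
})

test_that("motion tables round-trip and reject malformed headers", {
  f <- tempfile(fileext = ".mot")
  mt <- motion_table(c(0, 0.1, 0.2), cbind(a = c(1, 2, 3), b = c(-1, 0, 80)),
                     in_degrees = TRUE)
  write_motion(mt, f)
  mt2 <- read_motion(f)
  expect_equal(mt2$values, mt$values, tolerance = 1e-6)
  expect_true(mt2$in_degrees)
  # degree flag and constant values preserved
  mt3 <- motion_table(0:3 / 10, cbind(elv = rep(80, 4)))
  write_motion(mt3, f)
  expect_equal(unname(read_motion(f)$values[, 1]), rep(80, 4))
  # declared counts must match the block
  txt <- readLines(f)
  txt[sub("=.*", "", txt) == "nRows"] <- "nRows=99"
  writeLines(txt, f)
  expect_error(read_motion(f), "nRows")
  # non-increasing time is rejected at construction
  expect_error(motion_table(c(0, 0.1, 0.1), cbind(a = 1:3)),
               "strictly increasing")
})

test_that("trc marker files read into flattened columns", {
  f <- tempfile(fileext = ".trc")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\tmarkers.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits",
    "100\t100\t2\t2\tm",
    "Frame#\tTime\tACR\t\t\tELB\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2",
    "1\t0.00\t0.2\t1.1\t0.3\t0.1\t0.9\t0.25",
    "2\t0.01\t0.21\t1.1\t0.3\t0.1\t0.9\t0.25"), f)
  trc <- read_trc(f)
  expect_identical(colnames(trc$values),
                   c("ACR_x", "ACR_y", "ACR_z", "ELB_x", "ELB_y", "ELB_z"))
  expect_equal(unname(trc$values[1, "ACR_y"]), 1.1)
  expect_false(trc$in_degrees)
})

test_that("meshes round-trip in both formats and reject degenerate input", {
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  for (ext in c(".vtp", ".stl")) {
    f <- tempfile(fileext = ext)
    write_mesh(tet, f)
    back <- read_mesh(f)
    expect_equal(nrow(back$vertices), 4)
    expect_equal(nrow(back$faces), 4)
    expect_equal(oracle_signed_volume(back), oracle_signed_volume(tet),
                 tolerance = 1e-9)
  }
  # fixture humerus mesh: 8 vertices preserved through a round trip
  dir <- withr::local_tempdir()
  make_unilateral_fixture(dir = dir)
  hum <- read_mesh(file.path(dir, "humerus_r.vtp"))
  expect_equal(nrow(hum$vertices), 8)
  f <- file.path(dir, "hum2.vtp")
  write_mesh(hum, f)
  expect_equal(read_mesh(f), hum, tolerance = 1e-12)
  # empty meshes and non-triangular faces are format errors
  expect_error(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), "no vertices")
  quadvtp <- tempfile(fileext = ".vtp")
  writeLines(c('<VTKFile type="PolyData"><PolyData>',
               '<Piece NumberOfPoints="4" NumberOfPolys="1">',
               '<Points><DataArray>0 0 0 1 0 0 1 1 0 0 1 0</DataArray></Points>',
               '<Polys><DataArray Name="connectivity">0 1 2 3</DataArray>',
               '<DataArray Name="offsets">4</DataArray></Polys>',
               "</Piece></PolyData></VTKFile>"), quadvtp)
  expect_error(read_mesh(quadvtp), "non-triangular")
})
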