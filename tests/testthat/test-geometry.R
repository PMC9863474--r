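# landmark containers, annotation parsing, distance measurement

test_that("anatomy construction enforces its invariants", {
  a <- make_anatomy()
  expect_s3_class(a, "patient_anatomy")
  expect_identical(rownames(a$landmarks), landmark_names())

  # rows given in a different order are canonicalized
  lm <- a$landmarks[c(3, 1, 2), ]
  expect_identical(patient_anatomy("X", lm)$landmarks, a$landmarks)

  expect_error(make_anatomy(pv = c(0, 0, 0), svd = c(0, 0, 0)),
               "pairwise distinct")
  expect_error(make_anatomy(pv = c(NA, 0, 0)), "finite")
  expect_error(patient_anatomy("X", a$landmarks[1:2, ]), "3x3")
  lm_dup <- a$landmarks
  rownames(lm_dup)[2] <- "PV_CRANIAL_SUPERIOR_RIM"
  expect_error(patient_anatomy("X", lm_dup), "missing landmark")
})

test_that("annotation files round-trip and parse strictly", {
  path <- withr::local_tempfile(fileext = ".lmk")
  write_lmk_file(path, coords = list(
    PV_CRANIAL_SUPERIOR_RIM = c(1.5, -2, 3),
    SVD_SUPERIOR_RIM = c(0, 0, 10),
    AZYGOS_INFERIOR_RIM = c(0, 0, 25)
  ))
  a <- read_landmarks(path)
  expect_equal(unname(a$landmarks["PV_CRANIAL_SUPERIOR_RIM", ]),
               c(1.5, -2, 3))

  # write_landmarks() output re-reads to the same anatomy
  out <- withr::local_tempfile(fileext = ".lmk")
  write_landmarks(a, out)
  expect_equal(read_landmarks(out)$landmarks, a$landmarks)

  # error paths: missing name, duplicate, degenerate, non-finite, junk
  expect_error(read_landmarks(
    write_lmk_file(path, drop = "AZYGOS_INFERIOR_RIM")),
    "AZYGOS_INFERIOR_RIM")
  expect_error(read_landmarks(
    write_lmk_file(path, dup = "SVD_SUPERIOR_RIM")),
    "duplicate")
  expect_error(read_landmarks(write_lmk_file(path, coords = list(
    PV_CRANIAL_SUPERIOR_RIM = c(0, 0, 0),
    SVD_SUPERIOR_RIM = c(0, 0, 0),
    AZYGOS_INFERIOR_RIM = c(0, 0, 0)))),
    "pairwise distinct")
  expect_error(read_landmarks(write_lmk_file(path, coords = list(
    PV_CRANIAL_SUPERIOR_RIM = c(0, 0, "inf"),
    SVD_SUPERIOR_RIM = c(0, 0, 10),
    AZYGOS_INFERIOR_RIM = c(0, 0, 25)))),
    "non-finite")
  expect_error(read_landmarks(write_lmk_file(path,
    extra_lines = "unexpected_key 1")), "unknown key")
})

test_that("measure_anatomy computes the two Euclidean distances", {
  # 3-4-5 triangle on one side, straight 10 mm on the other
  m <- measure_anatomy(make_anatomy(pv = c(0, 0, 0), svd = c(3, 4, 0),
                                    azy = c(0, 0, 10)))
  expect_equal(m$d_pv_svd, 5)
  expect_equal(m$d_pv_azygos, 10)

  # boundary: vein right at the defect is a valid zero on one arm
  a <- make_anatomy(pv = c(0, 0, 0), svd = c(0, 0, 1e-5), azy = c(0, 0, 10))
  m <- measure_anatomy(a)
  expect_equal(m$d_pv_svd, 1e-5)
})

test_that("distances are rigid-motion invariant and homogeneous of degree 1", {
  set.seed(101)
  for (rep in 1:20) {
    lm <- matrix(runif(9, -30, 30), 3)
    rownames(lm) <- landmark_names()
    a <- patient_anatomy("R", lm)
    m0 <- measure_anatomy(a)

    # independent oracle: direct coordinate-difference norms
    expect_equal(m0$d_pv_svd, sqrt(sum((lm[1, ] - lm[2, ])^2)))
    expect_equal(m0$d_pv_azygos, sqrt(sum((lm[1, ] - lm[3, ])^2)))

    rot <- random_rotation()
    shift <- runif(3, -100, 100)
    moved <- t(rot %*% t(lm)) + matrix(shift, 3, 3, byrow = TRUE)
    rownames(moved) <- rownames(lm)
    m1 <- measure_anatomy(patient_anatomy("R", moved))
    expect_equal(m1$d_pv_svd, m0$d_pv_svd, tolerance = 1e-9)
    expect_equal(m1$d_pv_azygos, m0$d_pv_azygos, tolerance = 1e-9)

    s <- runif(1, 0.1, 5)
    m2 <- measure_anatomy(patient_anatomy("R", lm * s))
    expect_equal(m2$d_pv_svd, s * m0$d_pv_svd, tolerance = 1e-12)
    expect_equal(m2$d_pv_azygos, s * m0$d_pv_azygos, tolerance = 1e-12)
  }
})

test_that("snap_to_surface moves landmarks to nearest vertices", {
  verts <- rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 25), c(5, 5, 5))
  a <- make_anatomy(pv = c(0, 0, 0.4), svd = c(0.1, 0, 10),
                    azy = c(0, 0, 25))
  s <- snap_to_surface(a, verts)
  expect_equal(unname(s$landmarks["PV_CRANIAL_SUPERIOR_RIM", ]), c(0, 0, 0))
  disp <- attr(s, "snap_displacement_mm")
  expect_equal(unname(disp["PV_CRANIAL_SUPERIOR_RIM"]), 0.4)
  # landmark already on a vertex: identity, zero displacement
  expect_equal(unname(disp["AZYGOS_INFERIOR_RIM"]), 0)
  expect_equal(unname(s$landmarks["AZYGOS_INFERIOR_RIM", ]), c(0, 0, 25))

  expect_error(snap_to_surface(a, matrix(numeric(0), 0, 3)), "no vertices")
  # two landmarks nearest to the same vertex -> degenerate annotation
  close_pair <- make_anatomy(pv = c(0, 0, 0.1), svd = c(0, 0, -0.1),
                             azy = c(0, 0, 25))
  expect_error(snap_to_surface(close_pair, rbind(c(0, 0, 0), c(0, 0, 25))),
               "same mesh vertex")
})

test_that("STL round-trips through the ASCII writer and reader", {
  a <- make_anatomy(pv = c(0, 0, 20), svd = c(0, 0, 0), azy = c(0, 0, 40))
  fx <- sample_mesh_fixture(a, tube_radius_mm = 8)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(fx$mesh, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(fx$mesh$faces))
  # vertex sets match regardless of ordering
  key <- function(v) sort(apply(round(v, 6), 1, paste, collapse = ","))
  expect_identical(key(back$vertices), key(fx$mesh$vertices))
})

test_that("binary STL files are read identically to ASCII", {
  a <- make_anatomy(pv = c(0, 0, 15), svd = c(0, 0, 0), azy = c(0, 0, 30))
  mesh <- sample_mesh_fixture(a, tube_radius_mm = 5, n_segments = 8)$mesh
  ascii <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, ascii)

  # independently written binary STL (84-byte header + 50 bytes/triangle)
  bin <- withr::local_tempfile(fileext = ".stl")
  con <- file(bin, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    writeBin(numeric(3), con, size = 4, endian = "little")  # normal
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  close(con)

  m_bin <- read_stl(bin)
  m_asc <- read_stl(ascii)
  key <- function(v) sort(apply(round(v, 4), 1, paste, collapse = ","))
  expect_identical(key(m_bin$vertices), key(m_asc$vertices))
  expect_equal(nrow(m_bin$faces), nrow(m_asc$faces))
})
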