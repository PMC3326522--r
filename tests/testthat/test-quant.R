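# Frame alignment, domain-motion measurement, contact tables and
# signature-based state assignment.

test_that("frame alignment is exact for identity and pure z-rotations", {
  m <- fixModel("Rs1")
  self <- alignFrames(m, m, mode = "superpose-free-ring")
  expect_lt(max(abs(self$R - diag(3))), 1e-9)
  expect_lt(max(abs(self$t)), 1e-9)
  # a 13 degree z-rotation is recovered by the COM mode
  rot <- m
  co <- atomCoords(m) %*% t(rotZ(13))
  rot@atoms$x <- co[, 1]; rot@atoms$y <- co[, 2]; rot@atoms$z <- co[, 3]
  al <- alignFrames(m, rot, mode = "z-rotation-by-com")
  expect_equal(abs(al$z_rotation_deg), 13, tolerance = 1e-6)
  expect_lt(max(abs(atomCoords(al$b) - atomCoords(m))), 1e-6)
  # free-ring superposition zeroes the reference-ring residual
  mixed <- alignFrames(fixModel("Rs1"), fixModel("Rs2"),
                       mode = "superpose-free-ring")
  expect_lt(max(abs(atomCoords(mixed$b, ring = "bottom") -
                    atomCoords(fixModel("Rs1"), ring = "bottom"))), 1e-9)
})

test_that("domain motion measurement is exact for rigid transforms", {
  m <- fixModel("T")
  same <- measureDomainMotion(m, m, "apical")
  expect_equal(same$angle_deg, 0, tolerance = 1e-9)
  expect_equal(same$com_displacement_A, 0, tolerance = 1e-9)
  # a known 35 degree rotation about a known axis
  axis <- c(1, 2, 0.5) / sqrt(sum(c(1, 2, 0.5)^2))
  m2 <- m
  ap <- m@atoms$domain == "apical" & m@atoms$ring == "top" & m@atoms$subunit == 1
  co <- as.matrix(m@atoms[, c("x", "y", "z")])
  co[ap, ] <- rotateAbout(co[ap, ], c(10, 5, 40), axis, 35)
  m2@atoms$x <- co[, 1]; m2@atoms$y <- co[, 2]; m2@atoms$z <- co[, 3]
  mm <- measureDomainMotion(m, m2, "apical")
  expect_lt(abs(mm$angle_deg - 35), 1e-6)
  expect_gt(abs(sum(mm$axis * axis)), 1 - 1e-9)
  expect_error(measureDomainMotion(m, m, "nonexistent"), "at least 3")
})

test_that("measured rotations compose group-consistently along the trajectory", {
  mT <- fixModel("T"); m1 <- fixModel("Rs1"); m2 <- fixModel("Rs2")
  R01 <- measureDomainMotion(mT, m1, "apical")$R
  R12 <- measureDomainMotion(m1, m2, "apical")$R
  R02 <- measureDomainMotion(mT, m2, "apical")$R
  expect_lt(max(abs(R12 %*% R01 - R02)), 1e-6)
})

test_that("axis-angle agrees with an independent quaternion oracle", {
  set.seed(12)
  for (i in 1:100) {
    a <- matrix(rnorm(30), 10, 3)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 1, 179)
    b <- rotateAbout(a, rnorm(3), ax, ang) + matrix(rep(rnorm(3), each = 10), 10, 3)
    k <- kabsch(a, b)
    h <- hornSuperpose(a, b)
    expect_lt(max(abs(k$R - h$R)), 1e-6)
    expect_equal(rotationAxisAngle(k$R)$angle_deg, ang, tolerance = 1e-6)
  }
})

test_that("contact tables have zero spread under exact C7 symmetry", {
  tb <- contactDistances(fixModel("Rs1"))
  expect_true(all(tb$sd_A < 1e-6))
  # invariant under a global rigid transform
  m <- fixModel("Rs1")
  co <- sweep(atomCoords(m) %*% t(axisAngleMatrix(c(1, 1, 2), 17)),
              2, c(5, -3, 8), `+`)
  m2 <- m
  m2@atoms$x <- co[, 1]; m2@atoms$y <- co[, 2]; m2@atoms$z <- co[, 3]
  m2@symmetric <- FALSE     # rotation moves it off the z axis
  tb2 <- contactDistances(m2)
  expect_equal(tb$mean_A, tb2$mean_A, tolerance = 1e-9)
  # cutoff zero leaves nothing in contact
  expect_false(any(contactDistances(fixModel("T"), cutoffA = 0)$in_contact))
})

test_that("the T and Rs1 phantoms reproduce the published bridge switching", {
  key <- function(tb) paste(tb$a, tb$b, sep = "-")
  tbT <- contactDistances(fixModel("T"))
  tbR <- contactDistances(fixModel("Rs1"))
  inT <- setNames(tbT$in_contact, key(tbT))
  inR <- setNames(tbR$in_contact, key(tbR))
  expect_true(inT[["R197-E386"]]);  expect_false(inR[["R197-E386"]])
  expect_false(inT[["K80-E386"]]);  expect_true(inR[["K80-E386"]])
  expect_true(inT[["E255-K207"]]);  expect_false(inR[["E255-K207"]])
  expect_false(inT[["E255-K245"]]); expect_true(inR[["E255-K245"]])
})

test_that("the D83-K327 separation tracks the published trajectory", {
  d <- vapply(c("T", "Rs1", "Rs_open", "R_ES"), function(s) {
    tb <- contactDistances(fixModel(s))
    tb$mean_A[tb$a == "D83"]
  }, numeric(1))
  expect_equal(unname(d), c(8, 12.4, 15.7, 36), tolerance = 0.05)
})

test_that("inter-ring metrics report the A109 lengthening and antisymmetry", {
  mT <- fixModel("T", "T"); mR <- fixModel("Rs1", "T")
  same <- interringMetrics(mT, mT)
  expect_true(all(abs(same$change_A) < 1e-9))
  im <- interringMetrics(mT, mR)
  dA109 <- im$change_A[im$contact == "A109-A109"]
  expect_equal(dA109, 2, tolerance = 0.3)
  rev <- interringMetrics(mR, mT)
  expect_equal(rev$change_A, -im$change_A, tolerance = 1e-12)
})

test_that("contact signatures assign states with the documented tie contract", {
  inter <- canonicalContacts()
  inter <- inter[inter$scope == "intersubunit", ]
  aT <- assignStateFromContacts(contactDistances(fixModel("T"), inter))
  expect_equal(aT$state, "T")
  expect_gte(aT$margin, 1)
  aR <- assignStateFromContacts(contactDistances(fixModel("Rs1"), inter))
  expect_setequal(aR$state, c("Rs1", "Rs2"))
  aO <- assignStateFromContacts(contactDistances(fixModel("Rs_open"), inter))
  expect_equal(aO$state, "R-open family")
  # an all-false vector is the open family by definition
  tb <- contactDistances(fixModel("Rs_open"), inter)
  tb$in_contact <- FALSE
  expect_equal(assignStateFromContacts(tb)$state, "R-open family")
  # the Rd click-stop ladder resolves its distinct rungs
  for (s in c("Rd2", "Rd4")) {
    m <- buildStateModel(s, s)
    expect_equal(assignStateFromContacts(contactDistances(m, inter))$state, s)
  }
  a13 <- assignStateFromContacts(
    contactDistances(buildStateModel("Rd1", "Rd1"), inter))
  expect_setequal(a13$state, c("Rd1", "Rd3"))
})
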