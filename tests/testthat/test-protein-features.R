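test_that("normalizePSSM squashes into [0,1] with both methods", {
  p <- PSSMProfile("p", "AR", rbind(rep(0L, 20), rep(0L, 20)))
  expect_true(all(normalizePSSM(p) == 0.5))          # sigmoid fixed point

  sc <- matrix(0L, 2, 20); sc[1, 1] <- -5L; sc[2, 20] <- 5L
  p2 <- PSSMProfile("p", "AR", sc)
  mm <- normalizePSSM(p2, "minmax")
  expect_equal(unname(mm[1, 1]), 0)
  expect_equal(unname(mm[2, 20]), 1)

  p3 <- PSSMProfile("p", "AR", rbind(c(-2L, rep(0L, 19)),
                                     c(2L, rep(0L, 19))))
  sg <- normalizePSSM(p3)
  expect_equal(unname(sg[1, 1]), 1 / (1 + exp(2)), tolerance = 1e-4)
  expect_equal(unname(sg[2, 1]), 1 / (1 + exp(-2)), tolerance = 1e-4)

  expect_error(normalizePSSM(p, "minmax"), "degenerate",
               class = "dtiValidationError")
})

test_that("pssmBigram matches closed forms and flattening is row-major", {
  # L = 2, unit indicators at columns 1 and 2: only bigram(1,2) = 1/2
  N <- rbind(c(1, rep(0, 19)), c(0, 1, rep(0, 18)))
  b <- pssmBigram(N)
  expect_length(b, 400L)
  expect_equal(unname(b[["pssm_bg_1_2"]]), 0.5)
  expect_equal(sum(b), 0.5)
  expect_identical(names(b)[1:3], c("pssm_bg_1_1", "pssm_bg_1_2",
                                    "pssm_bg_1_3"))
  # constant matrix: every entry c^2 (L-1)/L
  for (L in c(3, 7)) {
    c0 <- 0.4
    bc <- pssmBigram(matrix(c0, L, 20))
    expect_equal(unname(bc), rep(c0^2 * (L - 1) / L, 400))
  }
  expect_error(pssmBigram(matrix(0.5, 1, 20)), "at least 2",
               class = "dtiValidationError")
})

test_that("compositions follow their defining counts and means", {
  sp <- randomStructuralProfile(4, seed = 1)
  sp@ss <- c("H", "H", "E", "C")
  expect_equal(unname(ssComposition(sp)), c(0.25, 0.25, 0.5))
  sp@ss <- rep("C", 4)
  expect_equal(unname(ssComposition(sp)), c(1, 0, 0))
  sp@asa <- c(10, 20, 30, 40)
  expect_equal(unname(asaComposition(sp)), 25)

  set.seed(42)
  sp50 <- randomStructuralProfile(50)
  cnt <- c(sum(sp50@ss == "C"), sum(sp50@ss == "E"), sum(sp50@ss == "H"))
  expect_equal(unname(ssComposition(sp50)), cnt / 50)
  expect_equal(sum(ssComposition(sp50)), 1)
})

test_that("torsionTransform takes sine and cosine of the file-order angles", {
  sp <- randomStructuralProfile(3, seed = 2)
  sp@angles <- matrix(0, 3, 4)
  expect_equal(unname(torsionTransform(sp)),
               cbind(matrix(0, 3, 4), matrix(1, 3, 4)))
  sp@angles[1, ] <- c(90, 30, -90, 180)
  tt <- torsionTransform(sp)
  expect_equal(unname(tt[1, ]),
               c(1, 0.5, -1, sin(pi), 0, sqrt(3) / 2, 0, -1),
               tolerance = 1e-12)
})

test_that("taComposition and ta/sp bigrams match brute-force oracles", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(5:30, 1)
    T <- matrix(runif(L * 8, -1, 1), L, 8)
    expect_equal(unname(taComposition(T)), colMeans(T), tolerance = 1e-12)
    expect_equal(unname(taBigram(T)), as.vector(t(oracleBigram(T))),
                 tolerance = 1e-12)
    sp <- randomStructuralProfile(L)
    expect_equal(unname(spBigram(sp)),
                 as.vector(t(oracleBigram(structProbs(sp)))),
                 tolerance = 1e-12)
    # normalization identity: entries of sp bigram sum to (L-1)/L
    expect_equal(sum(spBigram(sp)), (L - 1) / L, tolerance = 1e-12)
  }
})

test_that("single-residue composition is the transformed row itself", {
  sp <- randomStructuralProfile(1, seed = 9)
  expect_equal(unname(taComposition(torsionTransform(sp))),
               unname(torsionTransform(sp)[1, ]))
})

test_that("auto-covariances match the lagged brute-force oracle", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(12:40, 1)
    T <- matrix(runif(L * 8, -1, 1), L, 8)
    expect_equal(unname(taAutoCovariance(T, 10)),
                 oracleAutoCovariance(T, 10), tolerance = 1e-12)
    sp <- randomStructuralProfile(L)
    expect_equal(unname(spAutoCovariance(sp, 10)),
                 oracleAutoCovariance(structProbs(sp), 10),
                 tolerance = 1e-12)
  }
  # closed form for a constant column
  Tc <- matrix(0.3, 15, 8)
  ac <- taAutoCovariance(Tc, 10)
  for (k in 1:10)
    expect_equal(unname(ac[[paste0("ta_ac_", k, "_1")]]),
                 0.09 * (15 - k) / 15, tolerance = 1e-12)
  # boundary: L = 11, df = 10 keeps a single lag-10 product
  T11 <- matrix(runif(11 * 8, -1, 1), 11, 8)
  ac11 <- taAutoCovariance(T11, 10)
  expect_equal(unname(ac11[[paste0("ta_ac_10_3")]]),
               T11[1, 3] * T11[11, 3] / 11, tolerance = 1e-12)
  expect_error(taAutoCovariance(matrix(0, 10, 8), 10), "length",
               class = "dtiValidationError")
})

test_that("df = 1 auto-covariance scales like the bigram diagonal", {
  sp <- randomStructuralProfile(20, seed = 13)
  ac1 <- spAutoCovariance(sp, 1)
  bg <- spBigram(sp)
  diagNames <- paste0("sp_bg_", 1:3, "_", 1:3)
  expect_equal(unname(ac1), unname(bg[diagNames]), tolerance = 1e-12)
})

test_that("extractTargetFeatures concatenates groups to the documented lengths", {
  p <- makePSSM(length = 18, seed = 21)
  sp <- makeSPD(length = 18, seed = 22, sequence = proteinSequence(p))
  lens <- c(A = 400L, AB = 412L, ABC = 522L, ABCD = 595L)
  grp <- list(A = "A", AB = c("A", "B"), ABC = c("A", "B", "C"),
              ABCD = c("A", "B", "C", "D"))
  for (g in names(grp))
    expect_length(extractTargetFeatures(p, sp, groups = grp[[g]]),
                  lens[[g]])
  expect_error(extractTargetFeatures(p, sp, groups = c("B", "C")),
               "base group", class = "dtiValidationError")
  spOther <- makeSPD(length = 18, seed = 23)
  expect_error(extractTargetFeatures(p, spOther), "mismatch",
               class = "dtiValidationError")
})

test_that("compositions are permutation-invariant, bigrams are not", {
  set.seed(31)
  sp <- randomStructuralProfile(25)
  perm <- sample(25)
  spPerm <- StructuralProfile("p",
    paste(strsplit(proteinSequence(sp), "")[[1]][perm], collapse = ""),
    ssLabels(sp)[perm], asaValues(sp)[perm],
    torsionAngles(sp)[perm, ], structProbs(sp)[perm, ])
  expect_identical(ssComposition(spPerm), ssComposition(sp))
  expect_identical(asaComposition(spPerm), asaComposition(sp))
  expect_equal(taComposition(torsionTransform(spPerm)),
               taComposition(torsionTransform(sp)), tolerance = 1e-12)
  # adjacency features change under permutation (generic position swap)
  expect_false(isTRUE(all.equal(spBigram(spPerm), spBigram(sp))))
  # reversal transposes the bigram matrix up to the boundary terms: check
  # the exact identity L*bg(k,l) reversed == L*bg(l,k) forward
  rev <- seq(25, 1)
  spRev <- StructuralProfile("p",
    paste(strsplit(proteinSequence(sp), "")[[1]][rev], collapse = ""),
    ssLabels(sp)[rev], asaValues(sp)[rev],
    torsionAngles(sp)[rev, ], structProbs(sp)[rev, ])
  bgF <- matrix(spBigram(sp), 3, 3, byrow = TRUE)
  bgR <- matrix(spBigram(spRev), 3, 3, byrow = TRUE)
  expect_equal(bgR, t(bgF), tolerance = 1e-12)
})

test_that("angle features are invariant under adding full turns", {
  sp <- randomStructuralProfile(15, seed = 41)
  sp@angles <- matrix(runif(60, -180, 0), 15, 4)   # keep +360 in range
  spShift <- sp
  spShift@angles <- sp@angles + 360
  expect_equal(taComposition(torsionTransform(spShift)),
               taComposition(torsionTransform(sp)), tolerance = 1e-12)
  expect_equal(taBigram(torsionTransform(spShift)),
               taBigram(torsionTransform(sp)), tolerance = 1e-12)
  expect_equal(taAutoCovariance(torsionTransform(spShift)),
               taAutoCovariance(torsionTransform(sp)), tolerance = 1e-12)
})
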