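test_that("ADG is the least-squares slope of body weight on day", {
    days <- c(0, 14, 28, 42, 56, 70)
    expect_equal(computeADG(days, rep(400, 6)), 0)
    expect_equal(computeADG(days, 400 + 1.5 * days), 1.5)
    set.seed(1)
    bw <- 380 + 1.7 * days + rnorm(6, 0, 3)
    oracle <- sum((days - mean(days)) * (bw - mean(bw))) /
        sum((days - mean(days))^2)
    expect_equal(computeADG(days, bw), oracle)
    expect_error(computeADG(c(10, 10), c(400, 401)), "distinct weigh days")
})

test_that("metabolic weight is mean body weight to the 0.75 power", {
    expect_equal(computeMBW075(rep(400, 6)), 400^0.75)
    expect_equal(computeMBW075(c(300, 500)), 400^0.75)
    set.seed(2)
    bw <- runif(6, 350, 450)
    expect_equal(computeMBW075(bw), mean(bw)^0.75)
    expect_error(computeMBW075(c(400, -1)), "positive")
    expect_error(computeMBW075(numeric(0)), "empty")
})

test_that("residual traits match an explicit normal-equation solve", {
    pt <- computeResidualTraits(makeToyTrial(n = 10))
    tr <- feedTraits(pt)
    X <- cbind(1, tr$adg, tr$mbw075)
    betaDMI <- solve(t(X) %*% X, t(X) %*% tr$dmi)
    expect_equal(tr$rfi, drop(tr$dmi - X %*% betaDMI), tolerance = 1e-10)
    X2 <- cbind(1, tr$dmi, tr$mbw075)
    betaADG <- solve(t(X2) %*% X2, t(X2) %*% tr$adg)
    expect_equal(tr$rwg, drop(tr$adg - X2 %*% betaADG), tolerance = 1e-10)
    expect_equal(tr$rig, tr$rwg - tr$rfi)
    expect_equal(tr$fcr, tr$dmi / tr$adg)
})

test_that("residuals are orthogonal to the regressors and zero-mean", {
    pt <- computeResidualTraits(makeToyTrial(n = 20, seed = 4))
    tr <- feedTraits(pt)
    regressors <- list(rfi = list(tr$adg, tr$mbw075),
                       rwg = list(tr$dmi, tr$mbw075))
    for (nm in names(regressors)) {
        res <- tr[[nm]]
        expect_lt(abs(sum(res)), 1e-8 * sd(res) * nrow(tr))
        for (reg in regressors[[nm]])
            expect_lt(abs(sum(res * reg)),
                      1e-6 * sqrt(sum(res^2)) * sqrt(sum(reg^2)))
    }
})

test_that("intake exactly linear in gain and metabolic weight gives zero RFI", {
    pt <- computeResidualTraits(makeToyTrial(n = 8, seed = 5))
    tr <- feedTraits(pt)
    pt@dmi[] <- 2 + 1.5 * tr$adg + 0.09 * tr$mbw075
    pt@traits$dmi <- unname(pt@dmi)
    pt <- computeResidualTraits(pt)
    tr <- feedTraits(pt)
    expect_lt(max(abs(tr$rfi)), 1e-8)
    expect_equal(tr$rig, tr$rwg, tolerance = 1e-8)
})

test_that("rank-deficient trait regression names the collinear column", {
    pt <- makeToyTrial(n = 8, seed = 6)
    pt@traits$adg <- 1.5              # constant: collinear with the intercept
    pt@traits$mbw075 <- 90
    pt@traits$dmi <- unname(pt@dmi)
    expect_error(computeResidualTraits(pt), "collinear")
})

test_that("gain-slope outlier rule excludes exactly the planted animals", {
    pt <- makeToyTrial(n = 98, seed = 8)
    pt <- efnet:::.fillPerAnimal(pt)
    adg <- pt@traits$adg
    # plant two extreme low-gain animals at 4 SD below the mean
    low <- c(3, 50)
    pt@traits$adg[low] <- mean(adg) - 4 * sd(adg)
    out <- removeADGOutliers(pt, k = 2.5)
    tr <- feedTraits(out)
    z <- abs(pt@traits$adg - mean(pt@traits$adg)) / sd(pt@traits$adg)
    expect_identical(which(tr$excluded), which(z > 2.5))
    expect_true(all(low %in% which(tr$excluded)))

    # zero gain spread: nothing excluded (rule documented for SD = 0)
    same <- makeToyTrial(n = 6, seed = 9)
    same@traits$adg <- rep(1.5, 6)
    same@traits$mbw075 <- seq(85, 95, length.out = 6)
    expect_identical(
        sum(feedTraits(removeADGOutliers(same, refit = FALSE))$excluded), 0L)
    # degenerate threshold k = 0: every off-mean animal excluded
    off <- makeToyTrial(n = 6, seed = 9)
    off <- efnet:::.fillPerAnimal(off)
    outK0 <- removeADGOutliers(off, k = 0, refit = FALSE)
    expect_identical(feedTraits(outK0)$excluded,
                     off@traits$adg != mean(off@traits$adg))
})

test_that("extreme-group selection takes RIG tails with id tie-breaking", {
    pt <- makeToyTrial(n = 4, seed = 10)
    pt <- computeResidualTraits(pt)
    pt <- selectExtremeGroups(pt, nPerGroup = 2)
    tr <- feedTraits(pt)
    ord <- order(tr$rig, decreasing = TRUE)
    expect_setequal(tr$animal_id[tr$group == "HFE"], tr$animal_id[ord[1:2]])
    expect_setequal(tr$animal_id[tr$group == "LFE"], tr$animal_id[ord[3:4]])

    # boundary tie: two animals share the cutoff value; lower id is selected
    pt2 <- computeResidualTraits(makeToyTrial(n = 6, seed = 11))
    pt2@traits$rig <- c(2, 1, 1, -1, -2, -3)
    pt2 <- selectExtremeGroups(pt2, nPerGroup = 2)
    tr2 <- feedTraits(pt2)
    expect_identical(tr2$group[1:3], c("HFE", "HFE", "unassigned"))
    expect_error(selectExtremeGroups(pt2, nPerGroup = 4), "too few")
})

test_that("98 simulated animals split 20/20 with the rest unassigned", {
    trial <- simulateFeedTrial(trialSimConfig(seed = 3))
    pt <- computeFeedTraits(trial$phenotypes, nPerGroup = 20)
    tr <- feedTraits(pt)
    expect_identical(as.integer(table(tr$group[!tr$excluded])[c("HFE", "LFE")]),
                     c(20L, 20L))
})

test_that("group comparison routes by Shapiro-Wilk and matches pooled t", {
    set.seed(12)
    g1 <- rnorm(15, 10, 2); g2 <- rnorm(15, 11, 2)
    r <- compareGroups(c(g1, g2), rep(c("a", "b"), each = 15))
    expect_identical(r$test, "t")
    sp <- sqrt(((14) * var(g1) + (14) * var(g2)) / 28)
    tOracle <- (mean(g1) - mean(g2)) / (sp * sqrt(1 / 15 + 1 / 15))
    expect_equal(r$statistic, tOracle)

    same <- rnorm(10)
    rSame <- compareGroups(c(same, same), rep(c("a", "b"), each = 10))
    expect_gte(rSame$p, 0.99)

    expect_warning(
        rc <- compareGroups(c(rep(5, 5), rnorm(5)), rep(c("a", "b"), each = 5)),
        "zero within-group variance")
    expect_identical(rc$test, "wilcoxon")
})

test_that("heavy-tailed samples are routed to the rank-sum test", {
    routed <- vapply(1:50, function(s) {
        set.seed(s)
        v <- c(exp(rnorm(20, 0, 1.5)), rnorm(20, 2))
        compareGroups(v, rep(c("a", "b"), each = 20))$test
    }, character(1))
    expect_gte(mean(routed == "wilcoxon"), 0.9)
})

test_that("RFI-RIG correlation follows the closed form for the planted pair", {
    sx <- 0.90; sy <- 0.35; rho <- -0.60
    closed <- (rho * sx * sy - sx^2) /
        (sx * sqrt(sx^2 + sy^2 - 2 * rho * sx * sy))
    cors <- vapply(1:20, function(s) {
        p <- simulateResidualPairs(5000, seed = s)
        cor(p$rfi, computeRIG(p$rwg, p$rfi))
    }, numeric(1))
    expect_equal(mean(cors), closed, tolerance = 0.005)
})

test_that("the high-efficiency group converts feed better on average", {
    fcrDiff <- vapply(1:5, function(s) {
        trial <- simulateFeedTrial(trialSimConfig(seed = s))
        tr <- feedTraits(computeFeedTraits(trial$phenotypes, nPerGroup = 20))
        mean(tr$fcr[tr$group == "HFE"]) - mean(tr$fcr[tr$group == "LFE"])
    }, numeric(1))
    expect_true(all(fcrDiff < 0))
})
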