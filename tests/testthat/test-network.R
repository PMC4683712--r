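test_that("gene-gene correlation matches its definition", {
    set.seed(30)
    m <- matrix(rnorm(20), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    m <- rbind(m, dup = m["g1", ], neg = -m["g2", ])
    cc <- correlationMatrix(m)
    expect_equal(cc["dup", "g1"], 1)
    expect_equal(cc["neg", "g2"], -1)
    # entrywise covariance/SD oracle
    for (i in 1:3) for (j in (i + 1):4) {
        x <- m[i, ]; y <- m[j, ]
        expect_equal(cc[i, j],
                     sum((x - mean(x)) * (y - mean(y))) /
                         sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
    }
    expect_equal(cc, t(cc))
    mz <- rbind(m, flat = rep(1, 5))
    expect_error(correlationMatrix(mz), "flat")
})

test_that("unsigned soft-threshold adjacency follows |cor|^beta", {
    cc <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3)
    expect_equal(corAdjacency(cc, 3)[1, 2], 0.125)
    expect_equal(corAdjacency(cc, 1)[1, 3], 0.5)
    ends <- matrix(c(1, 0, 1, 0, 1, -1, 1, -1, 1), 3)
    for (b in c(1, 3, 7)) {
        a <- corAdjacency(ends, b)
        expect_equal(a[1, 2], 0)
        expect_equal(a[1, 3], 1)
        expect_equal(a[2, 3], 1)
    }
    expect_error(corAdjacency(cc, 0.5), "beta")
    # raising beta weakly shrinks every off-diagonal entry
    set.seed(31)
    r <- correlationMatrix(matrix(rnorm(80), nrow = 8))
    a2 <- corAdjacency(r, 2); a6 <- corAdjacency(r, 6)
    expect_true(all(a6 <= a2 + 1e-15))
})

test_that("topological overlap matches brute-force evaluation and its bounds", {
    # complete graph: all pairs share every neighbour
    full <- matrix(1, 3, 3)
    expect_true(all(topologicalOverlap(full) == 1))
    # star: two leaves share only the hub, overlap strictly positive
    star <- diag(4)
    star[1, 2:4] <- star[2:4, 1] <- 0.9
    tomStar <- topologicalOverlap(star)
    expect_gt(tomStar[2, 3], 0)
    expect_equal(tomStar[2, 3], (0.9 * 0.9 + 0) / (0.9 + 1 - 0))
    # random instances against the triple-loop oracle
    set.seed(32)
    for (rep in 1:25) {
        n <- sample(3:8, 1)
        a <- matrix(runif(n * n), n)
        a <- (a + t(a)) / 2
        diag(a) <- 1
        tom <- topologicalOverlap(a)
        expect_equal(tom, bruteTOM(a), tolerance = 1e-12)
        expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
        expect_equal(tom, t(tom))
    }
    bad <- matrix(runif(9), 3)
    expect_error(topologicalOverlap(bad), "symmetric")
})

test_that("soft-threshold choice agrees with an independent re-scan", {
    sim <- makeDefaultSim(seed = 33, nGenes = 300)
    expr <- computeFPKM(sim$sim$counts)
    scan <- suppressWarnings(pickSoftThreshold(expr, candidates = 1:12,
                                               r2Cut = 0.85))
    # independent oracle: recompute the binned log-log fit per candidate
    cc <- abs(correlationMatrix(expr)); diag(cc) <- 0
    r2 <- vapply(1:12, function(b) {
        k <- rowSums(cc^b)
        bins <- cut(k, 10)
        freq <- tapply(k, bins, length); mk <- tapply(k, bins, mean)
        ok <- !is.na(freq) & freq > 0 & mk > 0
        if (sum(ok) < 3) return(NA_real_)
        summary(lm(log10(freq[ok]) ~ log10(mk[ok])))$r.squared
    }, numeric(1))
    pass <- which(!is.na(r2) & r2 >= 0.85)
    oracle <- if (length(pass)) min(pass) else which.max(r2)
    expect_equal(chosenBeta(scan), oracle)
    expect_equal(scan@fits$r2, r2, tolerance = 1e-12)
    # forced singleton candidate is chosen regardless of fit
    expect_warning(one <- pickSoftThreshold(expr, candidates = 3,
                                            r2Cut = 0.999), "no candidate")
    expect_equal(chosenBeta(one), 3)
})

test_that("module detection separates planted blocks and enforces size", {
    m <- makeTwoBlockMatrix(blockSize = 40, nSamples = 12)
    net <- buildNetwork(m + abs(min(m)) + 1, beta = 6)
    mods <- clusterModules(net, minModuleSize = 30)
    lab <- moduleLabels(mods)
    expect_identical(sort(unique(lab)), c("blue", "turquoise"))
    expect_identical(unname(lab[1:40]), rep(lab[[1]], 40))
    expect_identical(unname(lab[41:80]), rep(lab[[41]], 40))
    # a 25-gene module stays below the size floor and goes grey
    small <- makeTwoBlockMatrix(blockSize = 25, nSamples = 12, seed = 8)
    netS <- buildNetwork(small + abs(min(small)) + 1, beta = 6)
    labS <- moduleLabels(clusterModules(netS, minModuleSize = 30))
    expect_true(all(labS == "grey"))
})

test_that("planted modules are recovered with high adjusted Rand index", {
    mods3 <- list(list(size = 50, cor = c(HFE = 0.8, LFE = 0.8), trait = 0.7),
                  list(size = 50, cor = c(HFE = 0.8, LFE = 0.8), trait = 0),
                  list(size = 50, cor = c(HFE = 0.8, LFE = 0.8), trait = 0))
    s <- makeDefaultSim(seed = 5, nGenes = 300, modules = mods3)
    net <- buildNetwork(computeFPKM(s$sim$counts), beta = 6)
    lab <- moduleLabels(clusterModules(net, minModuleSize = 30))
    truth <- s$sim$truth$module
    planted <- names(truth)[truth != "background"]
    expect_gte(mclust::adjustedRandIndex(lab[planted], truth[planted]), 0.9)
})

test_that("eigengenes maximise explained variance with stable orientation", {
    set.seed(34)
    base <- rnorm(10)
    m <- t(sapply(1:6, function(i) 2 * base + 5))  # identical member genes
    dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:10))
    lab <- setNames(rep("turquoise", 6), rownames(m))
    me <- moduleEigengenes(m, lab)
    expect_equal(abs(cor(me[, "turquoise"], base)), 1)
    expect_gte(cor(me[, "turquoise"], rowMeans(scale(t(m)))), 0)
    expect_equal(sum(me[, 1]^2), 1)

    mm <- makeTwoBlockMatrix(blockSize = 10, nSamples = 12)
    lab2 <- setNames(rep(c("turquoise", "blue"), each = 10), rownames(mm))
    me2 <- moduleEigengenes(mm, lab2)
    z <- t(scale(t(mm[1:10, ])))
    evar <- function(w) sum((z %*% (w / sqrt(sum(w^2))))^2)
    best <- evar(me2[, "turquoise"])
    set.seed(35)
    for (i in 1:100) expect_lte(evar(rnorm(12)), best + 1e-8)
    # flipping every member gene leaves trait correlations unchanged in size
    meF <- moduleEigengenes(rbind(-mm[1:10, ], mm[11:20, ]), lab2)
    trait <- rnorm(12)
    expect_equal(abs(cor(meF[, "turquoise"], trait)),
                 abs(cor(me2[, "turquoise"], trait)))
})

test_that("eigengene-trait correlation uses the exact t-transform", {
    set.seed(36)
    me <- matrix(rnorm(28), 14, 2,
                 dimnames = list(paste0("s", 1:14), c("turquoise", "blue")))
    traits <- data.frame(rfi = rnorm(14), rig = me[, 1] * 0.8 + rnorm(14, 0, 0.4))
    tc <- moduleTraitCorrelation(me, traits)
    for (i in seq_len(nrow(tc))) {
        r <- cor(me[, tc$module[i]], traits[[tc$trait[i]]])
        tstat <- r * sqrt(12 / (1 - r^2))
        expect_equal(tc$r[i], r)
        expect_equal(tc$p[i], 2 * pt(abs(tstat), 12, lower.tail = FALSE))
    }
    ident <- moduleTraitCorrelation(me, data.frame(rig = me[, 1]))
    expect_equal(ident$r[ident$module == "turquoise"], 1)
    expect_lt(ident$p[ident$module == "turquoise"], 1e-12)
})

test_that("trait-module gate applies strict r and inclusive p thresholds", {
    tc <- data.frame(module = c("a", "b", "c", "d"),
                     trait = "rig",
                     r = c(0.6, 0.5, 0.7, -0.8),
                     p = c(0.05, 0.01, 0.2, 0.1))
    sel <- selectTraitModules(tc, traits = "rig")
    expect_setequal(sel$module, c("a", "d"))   # b fails strict r, c fails p
    expect_identical(sel$pattern[sel$module == "d"], "-rig")
})

test_that("module membership is the gene-eigengene correlation with a two-sided gate", {
    mm <- makeTwoBlockMatrix(blockSize = 10, nSamples = 12)
    lab <- setNames(rep(c("turquoise", "blue"), each = 10), rownames(mm))
    me <- moduleEigengenes(mm, lab)
    kme <- moduleMembership(mm, me)
    expect_equal(kme, cor(t(mm), me))
    gene1 <- rbind(me1 = me[, "turquoise"] * 3 + 7, mm)
    labX <- c(me1 = "turquoise", lab)
    kmeX <- moduleMembership(gene1, me)
    expect_equal(kmeX["me1", "turquoise"], 1)
    kept <- filterByMembership(kmeX, labX, ownMin = 0.6, otherMax = 0.6)
    expect_true("me1" %in% kept$turquoise)
    # strong own membership is not enough when another module is close
    kmeFake <- rbind(g = c(turquoise = 0.7, blue = 0.65))
    expect_length(filterByMembership(kmeFake, c(g = "turquoise"))$turquoise, 0)
})

test_that("gene order permutation permutes network outputs consistently", {
    m <- makeTwoBlockMatrix(blockSize = 15, nSamples = 10)
    net <- buildNetwork(m, beta = 4)
    set.seed(37)
    perm <- sample(nrow(m))
    netP <- buildNetwork(m[perm, ], beta = 4)
    expect_equal(tomMatrix(netP), tomMatrix(net)[perm, perm])
    expect_equal(adjacencyMatrix(netP), adjacencyMatrix(net)[perm, perm])
})
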