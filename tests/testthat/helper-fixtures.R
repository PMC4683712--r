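# small fixtures built in code, shared across test files

# a noiseless linear-growth cohort with hand-set intake
makeToyTrial <- function(n = 10, seed = 99) {
    set.seed(seed)
    days <- c(0, 14, 28, 42, 56, 70)
    ids <- sprintf("A%02d", seq_len(n))
    bw0 <- runif(n, 340, 420)
    adg <- runif(n, 1.2, 2.4)
    bw <- data.frame(animal_id = rep(ids, each = length(days)),
                     day = rep(days, n),
                     bw_kg = rep(bw0, each = 6) + rep(adg, each = 6) * days)
    mbw <- (bw0 + adg * mean(days))^0.75
    dmi <- setNames(1 + 1.4 * adg + 0.08 * mbw + rnorm(n, 0, 0.5), ids)
    PhenotypeTable(bw, dmi)
}

# genes x samples matrix with two perfectly separable correlated blocks
makeTwoBlockMatrix <- function(blockSize = 40, nSamples = 12, seed = 7) {
    set.seed(seed)
    f1 <- rnorm(nSamples); f2 <- rnorm(nSamples)
    m <- rbind(
        t(sapply(seq_len(blockSize), function(i) f1 + rnorm(nSamples, 0, 0.2))),
        t(sapply(seq_len(blockSize), function(i) f2 + rnorm(nSamples, 0, 0.2))))
    dimnames(m) <- list(sprintf("g%03d", seq_len(2 * blockSize)),
                        sprintf("s%02d", seq_len(nSamples)))
    m
}

# default-structure simulation shared by the planted-recovery tests
makeDefaultSim <- function(seed, nGenes = 300, modules = NULL) {
    trial <- simulateFeedTrial(trialSimConfig(seed = seed))
    ph <- computeFeedTraits(trial$phenotypes, nPerGroup = 20)
    cfg <- if (is.null(modules)) exprSimConfig(nGenes = nGenes, seed = seed)
           else exprSimConfig(nGenes = nGenes, modules = modules, seed = seed)
    sim <- simulateExpression(cfg, ph)
    list(trial = trial, phenotypes = ph, sim = sim)
}

# brute-force TOM by explicit triple loop (independent of the matrix form)
bruteTOM <- function(a) {
    n <- nrow(a)
    tom <- diag(n)
    k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
}
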