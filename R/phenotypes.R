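#' Feeding-trial phenotype container
#'
#' Holds the raw trial records (body-weight series and mean daily dry-matter
#' intake per animal) and the derived feed-efficiency traits. Traits are
#' filled in by \code{\link{computeFeedTraits}} or stepwise by
#' \code{\link{computeResidualTraits}} and friends.
#'
#' @slot bw data.frame with columns animal_id, day, bw_kg (long format).
#' @slot dmi named numeric vector, mean daily dry-matter intake (kg/d) per
#'   animal.
#' @slot traits data.frame with one row per animal: adg, mbw075, dmi, fcr,
#'   rfi, rwg, rig, group, excluded, reason.
#' @slot fits list with the two trait regressions (\code{dmi} and \code{adg}),
#'   each as returned by the internal least-squares fitter.
#' @export
setClass("PhenotypeTable",
         representation(bw = "data.frame", dmi = "numeric",
                        traits = "data.frame", fits = "list"))

setValidity("PhenotypeTable", function(object) {
    msg <- NULL
    if (!all(c("animal_id", "day", "bw_kg") %in% names(object@bw)))
        msg <- c(msg, "bw needs columns animal_id, day, bw_kg")
    if (is.null(names(object@dmi)))
        msg <- c(msg, "dmi must be named by animal id")
    tr <- object@traits
    if (nrow(tr) && all(c("rfi", "rwg", "rig", "excluded") %in% names(tr))) {
        ok <- !tr$excluded & is.finite(tr$rig)
        if (any(ok) && max(abs(tr$rig[ok] - (tr$rwg[ok] - tr$rfi[ok]))) > 1e-8)
            msg <- c(msg, "rig must equal rwg - rfi for included animals")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PhenotypeTable", function(object) {
    ids <- unique(object@bw$animal_id)
    cat(sprintf("PhenotypeTable: %d animals, %d weigh days\n",
                length(ids), length(unique(object@bw$day))))
    if (nrow(object@traits) && "group" %in% names(object@traits)) {
        tab <- table(object@traits$group)
        cat("groups:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
    }
    invisible(object)
})

#' @rdname PhenotypeTable-class
#' @param bw data.frame with columns animal_id, day, bw_kg.
#' @param dmi named numeric vector of mean daily dry-matter intake (kg/d).
#' @return a \linkS4class{PhenotypeTable} with empty trait columns.
#' @export
PhenotypeTable <- function(bw, dmi) {
    bw$animal_id <- as.character(bw$animal_id)
    ids <- sort(unique(bw$animal_id))
    dmi <- dmi[ids]
    if (any(is.na(dmi)))
        stop("missing DMI for animals: ",
             paste(ids[is.na(dmi)], collapse = ", "))
    traits <- data.frame(animal_id = ids, adg = NA_real_, mbw075 = NA_real_,
                         dmi = as.numeric(dmi), fcr = NA_real_,
                         rfi = NA_real_, rwg = NA_real_, rig = NA_real_,
                         group = "unassigned", excluded = FALSE,
                         reason = "", stringsAsFactors = FALSE)
    new("PhenotypeTable", bw = bw, dmi = dmi, traits = traits, fits = list())
}

#' @rdname accessors
#' @export
feedTraits <- function(x) x@traits

#' @rdname accessors
#' @export
traitFits <- function(x) x@fits

#' Average daily gain from a body-weight series
#'
#' ADG is the ordinary least-squares slope of body weight on feeding day
#' (kg/d).
#'
#' @param day numeric vector of weigh days.
#' @param bw numeric vector of body weights (kg), same length.
#' @return slope in kg/d.
#' @examples
#' computeADG(c(0, 14, 28, 42, 56, 70), 400 + 1.5 * c(0, 14, 28, 42, 56, 70))
#' @export
computeADG <- function(day, bw) {
    stopifnot(length(day) == length(bw))
    if (length(unique(day)) < 2)
        stop("ADG slope undefined: need at least 2 distinct weigh days")
    d <- day - mean(day)
    sum(d * (bw - mean(bw))) / sum(d^2)
}

#' Metabolic weight
#'
#' Mean body weight over the weigh days raised to the 0.75 power (kg^0.75).
#'
#' @param bw numeric vector of body weights (kg), all positive.
#' @return mean(bw)^0.75.
#' @examples
#' computeMBW075(c(300, 500))  # 400^0.75
#' @export
computeMBW075 <- function(bw) {
    if (!length(bw)) stop("empty body-weight series")
    if (any(bw <= 0)) stop("body weights must be positive")
    mean(bw)^0.75
}

# least squares with explicit residual bookkeeping (QR via lm.fit)
.olsFit <- function(y, X, colnames) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
        stop("rank-deficient trait regression; collinear column(s): ",
             paste(colnames[bad], collapse = ", "))
    }
    beta <- qr.coef(qrX, y)
    fitted <- drop(X %*% beta)
    res <- y - fitted
    list(coefficients = stats::setNames(beta, colnames),
         residuals = res, fitted = fitted,
         r2 = 1 - sum(res^2) / sum((y - mean(y))^2), n = length(y))
}

.fillPerAnimal <- function(object) {
    tr <- object@traits
    bwsplit <- split(object@bw, object@bw$animal_id)
    for (i in seq_len(nrow(tr))) {
        s <- bwsplit[[tr$animal_id[i]]]
        if (length(unique(s$day)) < 3)
            stop("animal ", tr$animal_id[i],
                 ": fewer than 3 weigh days, slope not robust")
        tr$adg[i] <- computeADG(s$day, s$bw_kg)
        tr$mbw075[i] <- computeMBW075(s$bw_kg)
    }
    tr$fcr <- tr$dmi / tr$adg
    object@traits <- tr
    object
}

#' Residual feed-efficiency traits
#'
#' Fits, over the non-excluded animals, the two trait regressions
#' \deqn{DMI = \beta_0 + \beta_1 ADG + \beta_2 MBW^{0.75} + \epsilon_1}
#' \deqn{ADG = \beta_0 + \beta_1 DMI + \beta_2 MBW^{0.75} + \epsilon_2}
#' and stores RFI (\eqn{\epsilon_1}), RWG (\eqn{\epsilon_2}),
#' RIG = RWG - RFI and FCR = DMI/ADG. ADG and MBW^0.75 are (re)computed from
#' the body-weight series first if absent.
#'
#' @param object a \linkS4class{PhenotypeTable}.
#' @return the updated \linkS4class{PhenotypeTable}; the two regression fits
#'   (coefficients, residuals, R-squared) are in \code{traitFits()}.
#' @export
computeResidualTraits <- function(object) {
    if (anyNA(object@traits$adg)) object <- .fillPerAnimal(object)
    tr <- object@traits
    inc <- which(!tr$excluded)
    if (length(inc) < 4)
        stop("need at least 4 included animals to fit trait regressions")
    X1 <- cbind(intercept = 1, adg = tr$adg[inc], mbw075 = tr$mbw075[inc])
    fitDMI <- .olsFit(tr$dmi[inc], X1, colnames(X1))
    X2 <- cbind(intercept = 1, dmi = tr$dmi[inc], mbw075 = tr$mbw075[inc])
    fitADG <- .olsFit(tr$adg[inc], X2, colnames(X2))
    tr$rfi <- tr$rwg <- tr$rig <- NA_real_
    tr$rfi[inc] <- fitDMI$residuals
    tr$rwg[inc] <- fitADG$residuals
    tr$rig[inc] <- computeRIG(tr$rwg[inc], tr$rfi[inc])
    object@traits <- tr
    object@fits <- list(dmi = fitDMI, adg = fitADG)
    object
}

#' Remove average-daily-gain outliers
#'
#' Marks as excluded every animal whose ADG lies more than \code{k} standard
#' deviations from the cohort mean, then refits the residual traits on the
#' remaining animals. With zero ADG spread nothing is excluded.
#'
#' @param object a \linkS4class{PhenotypeTable} (ADG computed if absent).
#' @param k threshold in SD units (default 2.5).
#' @param refit recompute the residual traits on the cleaned cohort
#'   (default TRUE).
#' @return the updated \linkS4class{PhenotypeTable}.
#' @export
removeADGOutliers <- function(object, k = 2.5, refit = TRUE) {
    if (anyNA(object@traits$adg)) object <- .fillPerAnimal(object)
    tr <- object@traits
    mu <- mean(tr$adg)
    sdv <- stats::sd(tr$adg)
    if (sdv > 0) {
        out <- abs(tr$adg - mu) > k * sdv
        tr$excluded[out] <- TRUE
        tr$reason[out] <- sprintf("ADG outlier (|z| > %g)", k)
        tr$group[out] <- "unassigned"
    }
    object@traits <- tr
    if (refit) computeResidualTraits(object) else object
}

#' Select extreme efficiency groups by RIG
#'
#' Assigns the \code{nPerGroup} included animals with the highest RIG to the
#' high-feed-efficiency (HFE) group and the \code{nPerGroup} lowest to the
#' low-feed-efficiency (LFE) group; the remainder stay unassigned. Ties at a
#' group boundary are broken by ascending animal id.
#'
#' @param object a \linkS4class{PhenotypeTable} with RIG populated.
#' @param nPerGroup animals per group.
#' @return the updated \linkS4class{PhenotypeTable}.
#' @export
selectExtremeGroups <- function(object, nPerGroup) {
    tr <- object@traits
    inc <- which(!tr$excluded)
    if (anyNA(tr$rig[inc])) stop("RIG not populated; run computeResidualTraits")
    if (2 * nPerGroup > length(inc))
        stop("too few included animals for ", nPerGroup, " per group")
    tr$group <- "unassigned"
    ordHigh <- inc[order(-tr$rig[inc], tr$animal_id[inc])]
    ordLow <- inc[order(tr$rig[inc], tr$animal_id[inc])]
    tr$group[ordHigh[seq_len(nPerGroup)]] <- "HFE"
    tr$group[ordLow[seq_len(nPerGroup)]] <- "LFE"
    object@traits <- tr
    object
}

#' Full trait workflow
#'
#' Convenience wrapper: per-animal ADG/MBW^0.75, ADG outlier removal at
#' \code{outlierK} SD, residual trait regressions on the cleaned cohort, and
#' extreme-group selection by RIG.
#'
#' @param object a \linkS4class{PhenotypeTable}.
#' @param nPerGroup animals per extreme group (NULL to skip selection).
#' @param outlierK ADG outlier threshold in SD units.
#' @return the updated \linkS4class{PhenotypeTable}.
#' @export
computeFeedTraits <- function(object, nPerGroup = NULL, outlierK = 2.5) {
    object <- removeADGOutliers(object, k = outlierK)
    if (!is.null(nPerGroup))
        object <- selectExtremeGroups(object, nPerGroup)
    object
}

#' Residual intake and body-weight gain
#'
#' The combined efficiency trait: RIG = RWG - RFI. Efficient animals gain
#' more than predicted (high RWG) while eating less than predicted (low RFI),
#' so higher RIG means higher feed efficiency.
#'
#' @param rwg residual body-weight gain (kg/d).
#' @param rfi residual feed intake (kg/d).
#' @return RIG, on the kg/d scale.
#' @examples
#' computeRIG(rwg = -0.29, rfi = 1.24)
#' @export
computeRIG <- function(rwg, rfi) rwg - rfi

#' Normality-routed two-group comparison
#'
#' Tests each group for normality with Shapiro-Wilk; if both pass at
#' \code{alphaNormality} the groups are compared with a two-sided pooled
#' (Student) t-test, otherwise with the Mann-Whitney-Wilcoxon rank-sum test.
#' A group with zero variance forces the rank-sum route (the t statistic is
#' not defined there) with a warning.
#'
#' @param values numeric vector of trait values.
#' @param labels group label per value (exactly two levels).
#' @param alphaNormality Shapiro-Wilk alpha (default 0.05).
#' @param welch use the Welch (unequal-variance) t-test instead of the pooled
#'   form.
#' @return list with \code{test} ("t" or "wilcoxon"), \code{statistic},
#'   \code{p}, \code{shapiro_p} (per group) and the group means.
#' @export
compareGroups <- function(values, labels, alphaNormality = 0.05,
                          welch = FALSE) {
    labels <- as.character(labels)
    lev <- sort(unique(labels))
    if (length(lev) != 2) stop("exactly two groups required")
    g1 <- values[labels == lev[1]]
    g2 <- values[labels == lev[2]]
    if (length(g1) < 3 || length(g2) < 3)
        stop("each group needs at least 3 values")
    zeroVar <- stats::sd(g1) == 0 || stats::sd(g2) == 0
    if (zeroVar)
        warning("zero within-group variance; falling back to Mann-Whitney")
    sw <- if (zeroVar) stats::setNames(c(NA_real_, NA_real_), lev)
          else stats::setNames(c(stats::shapiro.test(g1)$p.value,
                                 stats::shapiro.test(g2)$p.value), lev)
    useT <- !zeroVar && all(sw >= alphaNormality)
    if (useT) {
        ht <- stats::t.test(g1, g2, var.equal = !welch)
        test <- "t"
    } else {
        ht <- suppressWarnings(stats::wilcox.test(g1, g2))
        test <- "wilcoxon"
    }
    list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_p = sw,
         means = stats::setNames(c(mean(g1), mean(g2)), lev))
}
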