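# Independent oracles: naive reference implementations used to check the
# package's vectorised code. Deliberately written as plain double loops.

# pair-counting GLCM oracle
naiveGLCM <- function(disc, levels, orientation = "horizontal",
                      distance = 1L, symmetric = TRUE) {
    counts <- matrix(0, levels, levels)
    nr <- nrow(disc); nc <- ncol(disc)
    dr <- if (orientation == "vertical") distance else 0L
    dc <- if (orientation == "horizontal") distance else 0L
    for (r in seq_len(nr)) {
        for (cc in seq_len(nc)) {
            r2 <- r + dr; c2 <- cc + dc
            if (r2 <= nr && c2 <= nc) {
                i <- disc[r, cc]; j <- disc[r2, c2]
                counts[i, j] <- counts[i, j] + 1
                if (symmetric) counts[j, i] <- counts[j, i] + 1
            }
        }
    }
    counts / sum(counts)
}

# direct evaluation of the five GLCM statistics from their formulas
naiveGLCMStats <- function(p) {
    n <- nrow(p)
    ent <- 0; contrast <- 0; hom <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
        contrast <- contrast + (i - j)^2 * p[i, j]
        hom <- hom + p[i, j] / (1 + abs(i - j))
    }
    pr <- rowSums(p); pc <- colSums(p)
    mur <- sum(seq_len(n) * pr); muc <- sum(seq_len(n) * pc)
    sr <- sqrt(sum((seq_len(n) - mur)^2 * pr))
    sc <- sqrt(sum((seq_len(n) - muc)^2 * pc))
    corr <- 0
    if (sr * sc > 0) {
        for (i in seq_len(n)) for (j in seq_len(n))
            corr <- corr + (i - mur) * (j - muc) * p[i, j]
        corr <- corr / (sr * sc)
    }
    vr <- sum((seq_len(n) - mur)^2 * pr)
    c(entropy = ent, contrast = contrast, correlation = corr,
      homogeneity = hom, variance = vr)
}

# population moments by direct summation
naiveMoments <- function(x) {
    v <- as.numeric(x); n <- length(v)
    mu <- sum(v) / n
    m2 <- sum((v - mu)^2) / n
    m3 <- sum((v - mu)^3) / n
    m4 <- sum((v - mu)^4) / n
    s <- sqrt(m2)
    c(mean = mu, sd = s,
      skewness = if (s == 0) 0 else m3 / s^3,
      kurtosis = if (s == 0) 0 else m4 / s^4 - 3)
}

# BFS flood fill: mask of the largest 4-connected component
floodFillLargest <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    labels <- matrix(0L, nr, nc)
    lab <- 0L
    for (sr in seq_len(nr)) for (sc in seq_len(nc)) {
        if (mask[sr, sc] && labels[sr, sc] == 0L) {
            lab <- lab + 1L
            queue <- list(c(sr, sc)); labels[sr, sc] <- lab
            while (length(queue)) {
                cur <- queue[[1]]; queue <- queue[-1]
                for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
                    r <- cur[1] + d[1]; cc <- cur[2] + d[2]
                    if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
                        mask[r, cc] && labels[r, cc] == 0L) {
                        labels[r, cc] <- lab
                        queue[[length(queue) + 1L]] <- c(r, cc)
                    }
                }
            }
        }
    }
    if (lab == 0L) return(matrix(FALSE, nr, nc))
    sizes <- tabulate(labels[labels > 0L], lab)
    labels == which.max(sizes)
}

# exhaustive rectangle enumeration via a summed-area table; returns the
# maximum-area all-TRUE rectangle with sides >= (minH, minW), ties broken
# by smallest row0 then col0; NULL when none exists
bruteRect <- function(mask, minH = 1L, minW = 1L) {
    nr <- nrow(mask); nc <- ncol(mask)
    if (nr < minH || nc < minW) return(NULL)
    sat <- apply(apply(mask * 1, 2, cumsum), 1, cumsum)  # sat[c, r]!
    area <- function(r0, c0, h, w) {   # 0-based row0/col0
        r1 <- r0 + h; c1 <- c0 + w     # 1-based exclusive bounds
        s <- sat[c1, r1]
        if (r0 > 0) s <- s - sat[c1, r0]
        if (c0 > 0) s <- s - sat[c0, r1]
        if (r0 > 0 && c0 > 0) s <- s + sat[c0, r0]
        s
    }
    best <- NULL; bestArea <- 0L
    for (r0 in 0:(nr - minH)) for (h in minH:(nr - r0)) {
        for (c0 in 0:(nc - minW)) for (w in minW:(nc - c0)) {
            if (area(r0, c0, h, w) == h * w) {
                a <- h * w
                if (a > bestArea ||
                    (a == bestArea &&
                     (r0 < best[1] || (r0 == best[1] && c0 < best[2])))) {
                    best <- c(r0, c0, h, w); bestArea <- a
                }
            }
        }
    }
    best
}

# a small hand-built TextureExperiment for regression/selection tests
makeTE <- function(X, targets, caseId = sprintf("case_%03d", seq_len(nrow(X))),
                   region = "L1") {
    if (is.null(colnames(X)))
        colnames(X) <- paste0("feat_", seq_len(ncol(X)))
    cd <- S4Vectors::DataFrame(caseId = caseId,
                               region = rep(region, length.out = nrow(X)),
                               missingFeature = NA_integer_)
    for (t in names(targets)) cd[[t]] <- targets[[t]]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = t(X)), colData = cd)
    te <- new("TextureExperiment", se)
    S4Vectors::metadata(te)$targetNames <- names(targets)
    te
}
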