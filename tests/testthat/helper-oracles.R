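## Independent oracles used by the tests. These deliberately do not share
## code with the package internals they check.

AA20h <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## --- brute-force per-position segment featurization oracle ---------------
## Averages property values position by position per segment, skipping X/U.
oracleFeaturizeTF <- function(sequence, valuesMatrix) {
    chars <- strsplit(sequence, "")[[1]]
    L <- length(chars)
    t <- floor(0.2 * L)
    segs <- list(chars[1:t], chars[(t + 1):(L - t)], chars[(L - t + 1):L])
    out <- numeric(0)
    for (seg in segs) {
        for (p in seq_len(nrow(valuesMatrix))) {
            tot <- 0; n <- 0
            for (ch in seg) {
                if (ch %in% c("X", "U")) next
                tot <- tot + valuesMatrix[p, ch]
                n <- n + 1
            }
            out <- c(out, tot / n)
        }
    }
    out
}

## --- Gotoh local alignment oracle (affine gaps, cost(k) = open + k*ext) --
## Returns the optimal local score and, via traceback, the identity
## (matches / alignment length) of one optimal alignment.
oracleLocalAlign <- function(a, b, subMat, open = 11, ext = 1) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    n <- length(x); m <- length(y)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(NEG, n + 1, m + 1)
    Iy <- matrix(NEG, n + 1, m + 1)
    for (i in 1 + seq_len(n)) {
        for (j in 1 + seq_len(m)) {
            s <- subMat[x[i - 1], y[j - 1]]
            M[i, j] <- s + max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                               Iy[i - 1, j - 1])
            Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
            Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
        }
    }
    best <- max(M)
    if (best <= 0)
        return(list(score = 0, identity = 0))
    hit <- which(M == best, arr.ind = TRUE)[1, ]
    i <- hit[1]; j <- hit[2]
    state <- "M"; matches <- 0; alen <- 0
    tol <- 1e-9
    repeat {
        if (state == "M") {
            alen <- alen + 1
            if (x[i - 1] == y[j - 1]) matches <- matches + 1
            prev <- M[i, j] - subMat[x[i - 1], y[j - 1]]
            i <- i - 1; j <- j - 1
            if (prev <= tol) break                # 0 reset: start of alignment
            if (abs(prev - M[i, j]) < tol) state <- "M"
            else if (abs(prev - Ix[i, j]) < tol) state <- "Ix"
            else state <- "Iy"
        } else if (state == "Ix") {               # gap in b, consumes a
            alen <- alen + 1
            fromM <- abs(Ix[i, j] - (M[i - 1, j] - (open + ext))) < tol
            i <- i - 1
            state <- if (fromM) "M" else "Ix"
        } else {                                  # gap in a, consumes b
            alen <- alen + 1
            fromM <- abs(Iy[i, j] - (M[i, j - 1] - (open + ext))) < tol
            j <- j - 1
            state <- if (fromM) "M" else "Iy"
        }
    }
    list(score = best, identity = matches / alen)
}

## --- direct log Gaussian density + log prior oracle ----------------------
oracleLogJoint <- function(x, mu, Sigma, logPrior) {
    d <- length(mu)
    -0.5 * d * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
        0.5 * drop(t(x - mu) %*% solve(Sigma) %*% (x - mu)) + logPrior
}

## --- small random study shared by several test files ---------------------
smallStudy <- function(seed = 3, effectSize = 2, nPositive = 30,
                       nNegativePerClass = 10, nProperties = 8) {
    genInteractionStudy(nProperties = nProperties, nPositive = nPositive,
                        nNegativePerClass = nNegativePerClass,
                        nDecoyTFs = 24, lengthRange = c(300L, 700L),
                        informativeProperties = 1:3,
                        effectSize = effectSize, seed = seed)
}

randomSequence <- function(L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(AA20h, L, replace = TRUE), collapse = "")
}
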