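# shared fixtures: everything is generated in code at test time

makeSpec <- function(mz, intensity = rep(1, length(mz)), id = "s",
                     role = "experiment", composition = numeric(),
                     temperature = NA_character_, iteration = NA_integer_) {
    Spectrum(mz, intensity, sourceId = id, role = role,
             composition = composition, temperature = temperature,
             iteration = iteration)
}

# independent closed-form GP posterior: plain solve() on the full
# covariance, no Cholesky, no code shared with the package internals
gpOracle <- function(model, Xnew) {
    p <- hyperParameters(model)
    tr <- trainingData(model)
    X <- tr$X; y <- tr$y
    kern <- function(A, B) {
        n1 <- nrow(A); n2 <- nrow(B)
        K <- matrix(0, n1, n2)
        for (i in seq_len(n1)) for (j in seq_len(n2)) {
            r <- sqrt(sum(((A[i, ] - B[j, ]) / p$lengthScales)^2))
            K[i, j] <- p$signalVar *
                (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
        }
        K
    }
    K <- kern(X, X) + diag(p$noiseVar + 1e-8, nrow(X))
    Ks <- kern(Xnew, X)
    Kinv <- solve(K)
    mu <- mean(y) + as.numeric(Ks %*% Kinv %*% (y - mean(y)))
    var <- p$signalVar - diag(Ks %*% Kinv %*% t(Ks))
    list(mean = mu, sd = sqrt(pmax(var, 0)))
}

cosineSim <- function(a, b) {
    if (sum(a^2) == 0 || sum(b^2) == 0) return(0)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# minimal centroided mzML with uncompressed 64-bit arrays
writeMinimalMzml <- function(path, mz, intensity) {
    enc <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                     size = 8))
    xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://x"/></cvList>
  <run id="run1">
    <spectrumList count="1" defaultDataProcessingRef="dp1">
      <spectrum index="0" id="scan=1" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
    </spectrumList>
  </run>
</mzML>', length(mz), nchar(enc(mz)), enc(mz), nchar(enc(intensity)),
          enc(intensity))
    writeLines(xml, path)
    invisible(path)
}

# a planted-archetype barcode matrix: nPer experiments per archetype, each
# expressing one disjoint fingerprint block, with optional bit-flip noise
plantedBarcode <- function(nArch = 4, nPer = 15, fpSize = 8,
                           flipProb = 0, seed = 1) {
    set.seed(seed)
    n <- nArch * fpSize
    m <- nArch * nPer
    M <- matrix(0L, m, n)
    for (a in seq_len(nArch)) {
        rows <- ((a - 1) * nPer + 1):(a * nPer)
        cols <- ((a - 1) * fpSize + 1):(a * fpSize)
        M[rows, cols] <- 1L
    }
    if (flipProb > 0) {
        flips <- matrix(runif(m * n) < flipProb, m, n)
        M <- abs(M - flips * 1L)
        mode(M) <- "integer"
    }
    dimnames(M) <- list(paste0("e", seq_len(m)),
                        as.character(200 + seq_len(n)))
    truth <- matrix(0, nArch, n, dimnames = list(NULL, colnames(M)))
    for (a in seq_len(nArch))
        truth[a, ((a - 1) * fpSize + 1):(a * fpSize)] <- 1
    # guard the barcode invariant: every column must appear somewhere
    keep <- colSums(M) > 0
    list(M = M[, keep, drop = FALSE], truth = truth[, keep, drop = FALSE])
}
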