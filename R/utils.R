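# Shared constants and small helpers.

# Standard amino-acid alphabet used throughout; X is scored/emitted as
# background, "-" is the gap symbol.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AAX <- c(AA20, "X")
AAGAP <- c(AAX, "-")

# Robinson-Robinson style background frequencies (order AA20), as used for
# null sequence sampling, insert emissions and log-odds scoring.
AA_BACKGROUND <- c(
    A = 0.0787, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0125,
    Q = 0.0395, E = 0.0633, G = 0.0684, H = 0.0227, I = 0.0593,
    L = 0.0976, K = 0.0519, M = 0.0239, F = 0.0396, P = 0.0482,
    S = 0.0683, T = 0.0541, W = 0.0109, Y = 0.0292, V = 0.0644)

# Ungapped BLOSUM62 Karlin-Altschul parameters for raw->bit conversion.
BLOSUM62_LAMBDA <- 0.267
BLOSUM62_K <- 0.041

.blosum_cache <- new.env(parent = emptyenv())

# BLOSUM62 over AA20 + X, with X scored 0 against everything.
blosumMatrix <- function() {
    if (is.null(.blosum_cache$S)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        B <- e$BLOSUM62[AA20, AA20]
        S <- matrix(0, 21L, 21L, dimnames = list(AAX, AAX))
        S[AA20, AA20] <- B
        .blosum_cache$S <- S
    }
    .blosum_cache$S
}

# Substitution matrix padded with a zero-scoring gap row/column, for
# profile-profile alignment of gapped columns.
blosumMatrixGapped <- function() {
    S <- blosumMatrix()
    S2 <- matrix(0, 22L, 22L, dimnames = list(AAGAP, AAGAP))
    S2[AAX, AAX] <- S
    S2
}

# Encode a protein string to 0-based integer codes into AAX (X = 20).
encodeProtein <- function(x, what = "sequence") {
    ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
    code <- match(ch, AAX) - 1L
    if (anyNA(code)) {
        bad <- ch[is.na(code)][1]
        stop("illegal character '", bad, "' in ", what, call. = FALSE)
    }
    code
}

decodeProtein <- function(code) paste(AAX[code + 1L], collapse = "")

logsumexp <- function(x) {
    x <- x[x > -Inf]
    if (!length(x)) return(-Inf)
    m <- max(x)
    m + log(sum(exp(x - m)))
}

# FNV-1a hash of a string, returned as 8 hex digits; used to stamp stage
# outputs with a configuration fingerprint.
fnv1a <- function(x) {
    bytes <- utf8ToInt(x) %% 256
    h <- 2166136261
    for (b in bytes) {
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), as.integer(b))
        h <- (h * 16777619) %% 4294967296
    }
    sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

configFingerprint <- function(config) {
    fnv1a(paste(deparse(config[order(names(config))]), collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derivation (kept below 2^31).
childSeed <- function(seed, i) {
    (as.numeric(seed) * 1103515245 + 12345 * as.numeric(i)) %% 2147483647
}

stopifnot_scalar_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(name, " must be a probability in [0, 1]", call. = FALSE)
    invisible(x)
}
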