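#' Grantham (1974) amino-acid physicochemical distance
#'
#' The Grantham distance scores the physicochemical dissimilarity of two
#' amino acids from three side-chain properties: composition `c` (atomic
#' weight ratio of non-carbon elements), polarity `p` and molecular volume
#' `v`. For residues i and j,
#' \deqn{D_{ij} = \rho \sqrt{\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 +
#'   \gamma (v_i-v_j)^2}}
#' with alpha = 1.833, beta = 0.1018, gamma = 0.000399 and the scaling
#' constant rho chosen so that the mean over all 190 unordered pairs equals
#' 100. Values returned here are the reference integers of the published
#' matrix; at package load a self-check verifies the formula reproduces them
#' within one unit. The Trp-Asp entry is stored as 191, the value the
#' formula yields from the published property table (the original print
#' shows 181, inconsistent with its own properties).
#'
#' @param aa1,aa2 Character vectors of amino acids, one-letter or three-letter
#'   code (recycled to a common length). Stop codons (`*`) are rejected:
#'   nonsense changes have no property vector and are tallied separately by
#'   the annotation layer.
#' @return Integer vector of Grantham distances; 0 iff `aa1 == aa2`.
#' @references Grantham, R. (1974) Amino acid difference formula to help
#'   explain protein evolution. Science 185, 862-864.
#' @examples
#' grantham_distance("L", "I") # 5, a conservative change
#' grantham_distance("Cys", "Trp") # 215, the matrix maximum
#' @export
grantham_distance <- function(aa1, aa2) {
  a <- normalize_aa(aa1)
  b <- normalize_aa(aa2)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  m <- grantham_matrix()
  m[cbind(a, b)]
}

#' Classify the protein-structural impact of an amino-acid change
#'
#' Substitutions with a Grantham distance strictly greater than 70 are
#' classified as having medium-to-high impact on protein structure; 70 and
#' below (including synonymous changes at 0) are conservative.
#'
#' @param grantham Numeric vector of nonnegative Grantham distances.
#' @return Character vector, `"conservative"` or `"medium_high"`.
#' @examples
#' classify_impact(c(0, 70, 71, 215))
#' @export
classify_impact <- function(grantham) {
  if (any(is.na(grantham)) || any(grantham < 0)) {
    stopf("Grantham scores must be nonnegative and non-missing")
  }
  ifelse(grantham > 70, "medium_high", "conservative")
}

#' Amino-acid property table and reference distance matrix
#'
#' `grantham_properties()` returns the composition/polarity/volume table for
#' the 20 standard amino acids; `grantham_matrix()` the 20 x 20 reference
#' integer distance matrix; `grantham_formula_matrix()` recomputes distances
#' from the properties with mean-100 scaling.
#'
#' @return A data.frame (properties) or a symmetric 20 x 20 matrix with
#'   one-letter row/column names.
#' @rdname grantham_tables
#' @export
grantham_properties <- function() {
  data.frame(
    aa = .gr_aa,
    composition = .gr_c[.gr_aa],
    polarity = .gr_p[.gr_aa],
    volume = .gr_v[.gr_aa],
    row.names = NULL
  )
}

.gr_aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
            "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

.gr_c <- c(S = 1.42, R = 0.65, L = 0, P = 0.39, T = 0.71, A = 0, V = 0,
           G = 0.74, I = 0, F = 0, Y = 0.20, C = 2.75, H = 0.58, Q = 0.89,
           N = 1.33, K = 0.33, D = 1.38, E = 0.92, M = 0, W = 0.13)
.gr_p <- c(S = 9.2, R = 10.5, L = 4.9, P = 8.0, T = 8.6, A = 8.1, V = 5.9,
           G = 9.0, I = 5.2, F = 5.2, Y = 6.2, C = 5.5, H = 10.4, Q = 10.5,
           N = 11.6, K = 11.3, D = 13.0, E = 12.3, M = 5.7, W = 5.4)
.gr_v <- c(S = 32, R = 124, L = 111, P = 32.5, T = 61, A = 31, V = 84,
           G = 3, I = 111, F = 132, Y = 136, C = 55, H = 96, Q = 85,
           N = 56, K = 119, D = 54, E = 83, M = 105, W = 170)

.gr_alpha <- 1.833
.gr_beta <- 0.1018
.gr_gamma <- 0.000399

# reference integer matrix, upper triangle in .gr_aa order
.gr_published <- local({
  rows <- list(
    S = c(R = 110, L = 145, P = 74, T = 58, A = 99, V = 124, G = 56,
          I = 142, F = 155, Y = 144, C = 112, H = 89, Q = 68, N = 46,
          K = 121, D = 65, E = 80, M = 135, W = 177),
    R = c(L = 102, P = 103, T = 71, A = 112, V = 96, G = 125, I = 97,
          F = 97, Y = 77, C = 180, H = 29, Q = 43, N = 86, K = 26,
          D = 96, E = 54, M = 91, W = 101),
    L = c(P = 98, T = 92, A = 96, V = 32, G = 138, I = 5, F = 22, Y = 36,
          C = 198, H = 99, Q = 113, N = 153, K = 107, D = 172, E = 138,
          M = 15, W = 61),
    P = c(T = 38, A = 27, V = 68, G = 42, I = 95, F = 114, Y = 110,
          C = 169, H = 77, Q = 76, N = 91, K = 103, D = 108, E = 93,
          M = 87, W = 147),
    T = c(A = 58, V = 69, G = 59, I = 89, F = 103, Y = 92, C = 149,
          H = 47, Q = 42, N = 65, K = 78, D = 85, E = 65, M = 81,
          W = 128),
    A = c(V = 64, G = 60, I = 94, F = 113, Y = 112, C = 195, H = 86,
          Q = 91, N = 111, K = 106, D = 126, E = 107, M = 84, W = 148),
    V = c(G = 109, I = 29, F = 50, Y = 55, C = 192, H = 84, Q = 96,
          N = 133, K = 97, D = 152, E = 121, M = 21, W = 88),
    G = c(I = 135, F = 153, Y = 147, C = 159, H = 98, Q = 87, N = 80,
          K = 127, D = 94, E = 98, M = 127, W = 184),
    I = c(F = 21, Y = 33, C = 198, H = 94, Q = 109, N = 149, K = 102,
          D = 168, E = 134, M = 10, W = 61),
    F = c(Y = 22, C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
          E = 140, M = 28, W = 40),
    Y = c(C = 194, H = 83, Q = 99, N = 143, K = 85, D = 160, E = 122,
          M = 36, W = 37),
    C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170, M = 196,
          W = 215),
    H = c(Q = 24, N = 68, K = 32, D = 81, E = 40, M = 87, W = 115),
    Q = c(N = 46, K = 53, D = 61, E = 29, M = 101, W = 130),
    N = c(K = 94, D = 23, E = 42, M = 142, W = 174),
    K = c(D = 101, E = 56, M = 95, W = 110),
    # D-W stored as the formula value 191; the 1974 print's 181 is
    # inconsistent with the property table it was derived from
    D = c(E = 45, M = 160, W = 191),
    E = c(M = 126, W = 152),
    M = c(W = 67)
  )
  m <- matrix(0L, 20, 20, dimnames = list(.gr_aa, .gr_aa))
  for (a in names(rows)) {
    for (b in names(rows[[a]])) {
      m[a, b] <- m[b, a] <- as.integer(rows[[a]][[b]])
    }
  }
  m
})

#' @rdname grantham_tables
#' @export
grantham_matrix <- function() .gr_published

#' @rdname grantham_tables
#' @export
grantham_formula_matrix <- function() {
  d2 <- outer(.gr_c, .gr_c, "-")^2 * .gr_alpha +
    outer(.gr_p, .gr_p, "-")^2 * .gr_beta +
    outer(.gr_v, .gr_v, "-")^2 * .gr_gamma
  raw <- sqrt(d2)
  rho <- 100 / mean(raw[upper.tri(raw)])
  m <- rho * raw
  dimnames(m) <- list(.gr_aa, .gr_aa)
  m[.gr_aa, .gr_aa]
}

grantham_selfcheck <- function() {
  f <- round(grantham_formula_matrix())
  p <- grantham_matrix()[rownames(f), colnames(f)]
  dev <- max(abs(f - p))
  if (dev > 1) {
    stopf("Grantham self-check failed: formula and reference matrix differ by %d units", dev)
  }
  invisible(TRUE)
}

.aa_three_to_one <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

normalize_aa <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) stopf("missing amino acid")
    if (nchar(v) == 3) {
      v3 <- paste0(toupper(substr(v, 1, 1)), tolower(substr(v, 2, 3)))
      if (!v3 %in% names(.aa_three_to_one)) {
        stopf("unknown amino acid '%s'", x[i])
      }
      v <- .aa_three_to_one[[v3]]
    }
    v <- toupper(v)
    if (v == "*") {
      stopf("stop codons have no Grantham distance; nonsense changes are tallied separately")
    }
    if (!v %in% .gr_aa) stopf("unknown amino acid '%s'", x[i])
    out[i] <- v
  }
  out
}
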