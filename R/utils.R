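# Shared constants and small geometry helpers.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", MSE = "M")

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL")

NUCLEIC_RESID <- c("DA", "DC", "DG", "DT", "DU", "DI", "A", "C", "G", "U", "I")
WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")
ION_RESID <- c("NA", "K", "MG", "CA", "CL", "ZN", "MN", "FE", "CU", "NI",
               "CO", "BR", "CD", "IOD", "CS", "LI")

aa1 <- function(resid) {
  out <- unname(AA3[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

aa3 <- function(one) {
  out <- unname(AA1TO3[toupper(one)])
  if (anyNA(out)) stop("invalid one-letter amino acid code: ",
                       paste(one[is.na(out)], collapse = ", "))
  out
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

## Dihedral angle a-b-c-d in degrees, IUPAC sign convention.
torsionAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

bondAngle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
}

## Natural extension of reference frame: place atom D bonded to C with bond
## length r, angle(B, C, D) = theta degrees and dihedral(A, B, C, D) = phi
## degrees.
placeAtom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- -phi * pi / 180  # IUPAC sign, consistent with torsionAngle()
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

## All pairwise Euclidean distances between rows of two coordinate matrices.
crossDist <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
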