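#' @import methods
#' @importFrom stats setNames
NULL

BASES <- c("A", "C", "G", "T")

## complement of a vector of single bases (vectorised, uppercase)
complementBase <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

#' The 96 canonical trinucleotide substitution classes
#'
#' Single-base substitutions are collapsed by reverse complement onto a
#' pyrimidine (C or T) reference base, giving 6 substitution types times
#' 16 flanking-base pairs = 96 classes. The fixed ordering used
#' throughout the package is substitution-major (C>A, C>G, C>T, T>A,
#' T>C, T>G), then 5' flank, then 3' flank, each in A, C, G, T order.
#'
#' Labels follow the \code{"<ref><alt>-<left>.<right>"} convention: for
#' example \code{"CT-G.A"} is a C-to-T substitution with G on the 5'
#' side and A on the 3' side.
#'
#' @return A data.frame with 96 rows and columns \code{ref}, \code{alt},
#'   \code{left}, \code{right}, \code{label}.
#' @examples
#' head(motifClassTable())
#' @export
motifClassTable <- function() {
  subs <- rbind(
    c("C", "A"), c("C", "G"), c("C", "T"),
    c("T", "A"), c("T", "C"), c("T", "G")
  )
  grid <- expand.grid(
    right = BASES, left = BASES, sub = seq_len(nrow(subs)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  ## expand.grid varies the first factor fastest; we want sub-major,
  ## then left, then right
  grid <- grid[order(grid$sub, match(grid$left, BASES),
                     match(grid$right, BASES)), ]
  out <- data.frame(
    ref = subs[grid$sub, 1],
    alt = subs[grid$sub, 2],
    left = grid$left,
    right = grid$right,
    stringsAsFactors = FALSE
  )
  out$label <- paste0(out$ref, out$alt, "-", out$left, ".", out$right)
  rownames(out) <- NULL
  out
}

.motifEnv <- new.env(parent = emptyenv())

motifTableCached <- function() {
  if (is.null(.motifEnv$tab)) .motifEnv$tab <- motifClassTable()
  .motifEnv$tab
}

#' Labels of the 96 motif classes in the package's fixed order
#' @return Character vector of length 96.
#' @export
motifClassLabels <- function() motifTableCached()$label

#' Collapse a raw substitution context onto its canonical motif class
#'
#' A substitution observed on the reference "+" strand with a purine
#' (A/G) reference base is replaced by its reverse complement: ref and
#' alt are complemented and the flanks are swapped and complemented.
#' Substitutions with a pyrimidine reference are already canonical.
#' The map is exactly 2-to-1 from the 192 raw contexts onto 96 classes.
#'
#' @param ref,alt,left,right Character vectors of single bases in
#'   \code{A,C,G,T}; \code{ref != alt} elementwise. Recycled to a
#'   common length.
#' @return Character vector of canonical class labels such as
#'   \code{"CT-G.A"}.
#' @examples
#' canonicalizeMotif("C", "T", "G", "A")  # "CT-G.A"
#' canonicalizeMotif("G", "A", "T", "C")  # also "CT-G.A"
#' @export
canonicalizeMotif <- function(ref, alt, left, right) {
  n <- max(length(ref), length(alt), length(left), length(right))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  left <- toupper(rep_len(left, n)); right <- toupper(rep_len(right, n))
  ok <- ref %in% BASES & alt %in% BASES & left %in% BASES & right %in% BASES
  if (!all(ok))
    stop("canonicalizeMotif: bases must be one of A, C, G, T")
  if (any(ref == alt))
    stop("canonicalizeMotif: ref and alt must differ")
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    r2 <- complementBase(ref[flip]); a2 <- complementBase(alt[flip])
    l2 <- complementBase(right[flip]); rr2 <- complementBase(left[flip])
    ref[flip] <- r2; alt[flip] <- a2
    left[flip] <- l2; right[flip] <- rr2
  }
  paste0(ref, alt, "-", left, ".", right)
}

#' Convert between native and COSMIC motif-class notation
#'
#' COSMIC writes the class \code{"CT-G.A"} as \code{"G[C>T]A"}.
#'
#' @param x Character vector of labels.
#' @return Character vector of converted labels.
#' @examples
#' nativeToCosmic("CT-G.A")  # "G[C>T]A"
#' cosmicToNative("G[C>T]A") # "CT-G.A"
#' @export
nativeToCosmic <- function(x) {
  m <- regmatches(x, regexec("^([ACGT])([ACGT])-([ACGT])\\.([ACGT])$", x))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("not a native motif label: ", paste(x[bad], collapse = ", "))
  vapply(m, function(p) paste0(p[4], "[", p[2], ">", p[3], "]", p[5]), "")
}

#' @rdname nativeToCosmic
#' @export
cosmicToNative <- function(x) {
  m <- regmatches(x, regexec(
    "^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", x))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("not a COSMIC motif label: ", paste(x[bad], collapse = ", "))
  vapply(m, function(p) paste0(p[3], p[4], "-", p[2], ".", p[5]), "")
}

#' Split a gene-motif label into gene and motif class
#'
#' Gene-motif labels concatenate a gene identifier with a motif class,
#' e.g. \code{"KRAS-CT-A.G"}. The motif class is the trailing
#' \code{"XY-L.R"} block; everything before it is the gene identifier.
#'
#' @param label Character vector of gene-motif labels.
#' @return data.frame with columns \code{gene} and \code{motif}.
#' @export
splitGeneMotif <- function(label) {
  m <- regmatches(label,
    regexec("^(.*)-([ACGT][ACGT]-[ACGT]\\.[ACGT])$", label))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("not a gene-motif label: ", paste(label[bad], collapse = ", "))
  data.frame(
    gene = vapply(m, `[`, "", 2L),
    motif = vapply(m, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

geneMotifLabel <- function(gene, motif) paste0(gene, "-", motif)
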