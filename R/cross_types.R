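#' Segregation (cross) types of an outbred F1 full-sib family
#'
#' In an F1 progeny of two outbred, heterozygous parents a biallelic or
#' triallelic SNP segregates according to the parental genotype pair: the six
#' informative cross types are \code{aaxab}, \code{aaxbc}, \code{abxaa},
#' \code{abxcc} (all 1:1), \code{abxab} (1:2:1) and \code{abxac} (1:1:1:1).
#' Genotype classes are unphased, parent-agnostic letter pairs normalized to
#' alphabetical order; the first parent in a code is the female.
#'
#' @return A data frame with one row per cross type: \code{code},
#'   \code{female}, \code{male} (parental genotype classes), \code{classes}
#'   (list column of expected offspring classes) and \code{ratio} (list
#'   column of integer segregation proportions).
#' @examples
#' cross_types()
#' @export
cross_types <- function() {
  data.frame(
    code    = c("aaxab", "aaxbc", "abxaa", "abxcc", "abxab", "abxac"),
    female  = c("aa", "aa", "ab", "ab", "ab", "ab"),
    male    = c("ab", "bc", "aa", "cc", "ab", "ac"),
    classes = I(list(
      c("aa", "ab"),
      c("ab", "ac"),
      c("aa", "ab"),
      c("ac", "bc"),
      c("aa", "ab", "bb"),
      c("aa", "ab", "ac", "bc")
    )),
    ratio = I(list(
      c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L),
      c(1L, 2L, 1L), c(1L, 1L, 1L, 1L)
    )),
    stringsAsFactors = FALSE
  )
}

# normalize "ba" -> "ab"; vectorized, NA passes through
normalize_geno_class <- function(x) {
  out <- vapply(x, function(g) {
    if (is.na(g)) return(NA_character_)
    paste(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

# normalize seg-type spellings: "aa x ab", "aa×ab" -> "aaxab"
normalize_seg_type <- function(x) {
  x <- gsub("[*[:space:]]", "", x)
  gsub("×", "x", x)
}

#' Expected offspring classes for a cross type code
#'
#' @param code Cross type code, e.g. \code{"aaxab"}.
#' @return Character vector of expected offspring genotype classes.
#' @keywords internal
cross_classes <- function(code) {
  ct <- cross_types()
  i <- match(normalize_seg_type(code), ct$code)
  if (is.na(i)) stop("unknown segregation type: ", code)
  ct$classes[[i]]
}

cross_ratio <- function(code) {
  ct <- cross_types()
  i <- match(normalize_seg_type(code), ct$code)
  if (is.na(i)) stop("unknown segregation type: ", code)
  ct$ratio[[i]]
}

#' Infer the cross type from a pair of parental genotype classes
#'
#' Classifies the parental genotype pair at a locus into one of the six
#' informative full-sib cross types, or flags the locus as non-segregating
#' when the cross produces a single offspring class (both parents
#' homozygous). The first parent is the female, so \code{("aa","ab")} maps to
#' \code{aaxab} while \code{("ab","aa")} maps to \code{abxaa}. Parental
#' alleles are relabelled to the canonical letters of the matching code; the
#' returned \code{mapping} translates original allele letters to canonical
#' ones so offspring calls can be normalized consistently.
#'
#' @param female,male Parental genotype classes as two-letter strings
#'   (e.g. \code{"ab"}); allele symbols are arbitrary single characters.
#' @return An object of class \code{cross_type}: a list with \code{code}
#'   (\code{NA} for a non-segregating cross), \code{segregating},
#'   \code{classes}, \code{ratio} and \code{mapping} (named character vector
#'   from original to canonical allele letters).
#' @examples
#' infer_cross_type("aa", "ab")          # 1:1, classes aa/ab
#' infer_cross_type("ab", "ac")$ratio    # 1:1:1:1
#' infer_cross_type("aa", "aa")$segregating
#' @export
infer_cross_type <- function(female, male) {
  if (is.na(female) || is.na(male))
    stop("both parental calls must be non-missing")
  f <- sort(strsplit(female, "")[[1]])
  m <- sort(strsplit(male, "")[[1]])
  if (length(f) != 2L || length(m) != 2L)
    stop("parental genotype classes must be two-allele strings")
  alleles <- unique(c(f, m))
  if (length(alleles) > 3L)
    stop("parental pair (", female, ", ", male,
         ") is not representable with at most 3 alleles")
  het_f <- f[1] != f[2]
  het_m <- m[1] != m[2]

  no_seg <- function() {
    structure(list(code = NA_character_, segregating = FALSE,
                   classes = character(0), ratio = integer(0),
                   mapping = NULL),
              class = "cross_type")
  }
  if (!het_f && !het_m) return(no_seg())

  if (!het_f && het_m) {
    if (f[1] %in% m) {        # aa x ab
      code <- "aaxab"
      map <- c(f[1], setdiff(m, f[1]))
    } else {                  # aa x bc
      code <- "aaxbc"
      map <- c(f[1], m)
    }
  } else if (het_f && !het_m) {
    if (m[1] %in% f) {        # ab x aa
      code <- "abxaa"
      map <- c(m[1], setdiff(f, m[1]))
    } else {                  # ab x cc
      code <- "abxcc"
      map <- c(f, m[1])
    }
  } else {
    shared <- intersect(f, m)
    if (length(shared) == 2L) {   # ab x ab
      code <- "abxab"
      map <- f
    } else {                      # ab x ac (one shared allele)
      code <- "abxac"
      map <- c(shared, setdiff(f, shared), setdiff(m, shared))
    }
  }
  mapping <- stats::setNames(letters[seq_along(map)], map)
  structure(list(code = code, segregating = TRUE,
                 classes = cross_classes(code), ratio = cross_ratio(code),
                 mapping = mapping),
            class = "cross_type")
}

# translate a genotype class through an allele mapping; NA if any allele
# is absent from the mapping (Mendelian-impossible under the cross)
map_geno_class <- function(class, mapping) {
  if (is.na(class)) return(NA_character_)
  al <- strsplit(class, "")[[1]]
  if (!all(al %in% names(mapping))) return(NA_character_)
  paste(sort(unname(mapping[al])), collapse = "")
}
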