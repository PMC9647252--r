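#' @keywords internal
"_PACKAGE"

# Chain arity by lipid class. Sphingolipids (SM/CER/HCER/LCER/DCER) are
# written with two chains (sphingoid base + N-acyl) in the same c:d syntax.
.LIPID_CLASS_ARITY <- c(
  TAG = 3L,
  DAG = 2L, PE = 2L, PC = 2L, PI = 2L, SM = 2L,
  CER = 2L, HCER = 2L, LCER = 2L, DCER = 2L,
  MAG = 1L, LPE = 1L, LPC = 1L, CE = 1L, FFA = 1L
)

#' Known lipid classes
#'
#' @return Character vector of the 14 quantified lipid sub-classes plus FFA.
#' @export
lipid_classes <- function() names(.LIPID_CLASS_ARITY)

#' Parse a lipid species label
#'
#' Accepts the `CLASS(c:d_c:d...)` nomenclature with common dialects:
#' optional whitespace (`"PE (16:0_18:2)"`), `/` as chain separator,
#' sphingoid-base prefixes (`"SM(d18:1/16:0)"`), and the summed TAG
#' dialect `"TAG52:3"` / `"TAG(52:3)"` which records only total carbons
#' and double bonds. Chains are canonicalised by sorting, since the
#' nomenclature lists side chains without positional assignment.
#'
#' @param label Character scalar, e.g. `"PE(16:0_18:2)"`.
#' @return A `lipid_name` object with fields `lipid_class`, `chains`
#'   (integer matrix, columns `carbons`/`double_bonds`), `summed`
#'   (logical; `TRUE` for the read-only summed-TAG dialect), `total`
#'   (carbons/double bonds summed over chains) and `raw_label`.
#' @examples
#' parse_lipid_name("PE (16:0_18:2)")
#' parse_lipid_name("TAG(16:0_18:1_18:2)")$total
#' @export
parse_lipid_name <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  raw <- label
  s <- gsub("\\s+", "", label)

  # class token = leading letters
  cls <- sub("^([A-Za-z]+).*$", "\\1", s)
  cls_up <- toupper(cls)
  if (!cls_up %in% names(.LIPID_CLASS_ARITY)) {
    stop("unknown lipid class token: '", cls, "' in label '", label, "'",
         call. = FALSE)
  }
  body <- substr(s, nchar(cls) + 1L, nchar(s))
  body <- gsub("^\\(|\\)$", "", body)
  if (!nzchar(body)) stop("no chain specification in label '", label, "'",
                          call. = FALSE)

  parts <- strsplit(body, "[_/]")[[1]]
  # strip sphingoid-base prefixes like d18:1, t18:0
  parts <- sub("^[dtm]", "", parts)
  if (!all(grepl("^[0-9]+:[0-9]+$", parts))) {
    stop("malformed chain specification in label '", label, "'", call. = FALSE)
  }
  mat <- t(vapply(strsplit(parts, ":", fixed = TRUE),
                  function(p) as.integer(p), integer(2)))
  colnames(mat) <- c("carbons", "double_bonds")

  arity <- .LIPID_CLASS_ARITY[[cls_up]]
  summed <- FALSE
  if (nrow(mat) != arity) {
    # summed-composition dialect: one c:d pair for a multi-chain class,
    # total carbons too large for a single chain (e.g. TAG52:3)
    if (nrow(mat) == 1L && arity > 1L && mat[1, "carbons"] > 30L) {
      summed <- TRUE
    } else {
      stop("arity mismatch for class ", cls_up, ": expected ", arity,
           " chain(s), got ", nrow(mat), " in label '", label, "'",
           call. = FALSE)
    }
  }
  if (!summed) {
    if (any(mat[, "carbons"] < 2L))
      stop("chain with fewer than 2 carbons in label '", label, "'",
           call. = FALSE)
    if (any(mat[, "double_bonds"] > mat[, "carbons"]))
      stop("more double bonds than carbons in label '", label, "'",
           call. = FALSE)
    ord <- order(mat[, "carbons"], mat[, "double_bonds"])
    mat <- mat[ord, , drop = FALSE]
  }

  structure(
    list(
      lipid_class = cls_up,
      chains = if (summed) NULL else mat,
      summed = summed,
      total = c(carbons = sum(mat[, "carbons"]),
                double_bonds = sum(mat[, "double_bonds"])),
      raw_label = raw
    ),
    class = "lipid_name"
  )
}

#' Canonical label for a parsed lipid
#'
#' @param x A `lipid_name`.
#' @return `"CLASS(c:d_c:d...)"` with chains sorted; summed-TAG dialect is
#'   formatted as `"CLASS(C:D)"` with totals.
#' @export
format_lipid_name <- function(x) {
  stopifnot(inherits(x, "lipid_name"))
  if (x$summed) {
    sprintf("%s(%d:%d)", x$lipid_class, x$total[["carbons"]],
            x$total[["double_bonds"]])
  } else {
    chains <- apply(x$chains, 1L,
                    function(ch) sprintf("%d:%d", ch[1], ch[2]))
    sprintf("%s(%s)", x$lipid_class, paste(chains, collapse = "_"))
  }
}

#' @export
format.lipid_name <- function(x, ...) format_lipid_name(x)

#' @export
print.lipid_name <- function(x, ...) {
  cat("<lipid_name> ", format_lipid_name(x),
      if (x$summed) " [summed dialect]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
`==.lipid_name` <- function(e1, e2) {
  identical(e1$lipid_class, e2$lipid_class) &&
    identical(e1$summed, e2$summed) &&
    identical(unname(e1$total), unname(e2$total)) &&
    (e1$summed || identical(unname(e1$chains), unname(e2$chains)))
}

#' Canonicalise a vector of lipid labels
#'
#' @param labels Character vector of labels in any accepted dialect.
#' @return Character vector of canonical labels.
#' @export
canonical_lipid_labels <- function(labels) {
  vapply(labels, function(l) format_lipid_name(parse_lipid_name(l)),
         character(1), USE.NAMES = FALSE)
}

#' Lipid class of each label
#'
#' @param labels Character vector of species labels.
#' @return Character vector of class tokens.
#' @export
lipid_class_of <- function(labels) {
  vapply(labels, function(l) parse_lipid_name(l)$lipid_class,
         character(1), USE.NAMES = FALSE)
}
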