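# Exclusive-intersection (UpSet) decomposition of the per-comparison gene
# sets, and the five named intersection categories of the study design.

#' Decompose named gene sets into exclusive intersections
#'
#' For every nonempty membership pattern P (a subset of the set names), the
#' class of P holds exactly the genes belonging to all sets in P and to no
#' other set - UpSet semantics. Empty classes are omitted. The classes
#' partition the union of the inputs, and the decomposition does not depend
#' on the listing order of the sets: pattern keys are the member set names
#' sorted alphabetically and joined with `"&"`.
#'
#' @param sets Named list of character vectors; names must be unique and
#'   non-empty.
#' @return An object of class `overlap_decomposition`: list with `sets` (the
#'   inputs, duplicates dropped) and `classes` (named list, pattern key ->
#'   sorted gene vector).
#' @export
#' @examples
#' upset_decompose(list(A = c("x", "y"), B = c("y", "z")))$classes
upset_decompose <- function(sets) {
  if (!is.list(sets) || length(sets) == 0) {
    stop("`sets` must be a non-empty named list", call. = FALSE)
  }
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every set must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    stop("duplicate set name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    return(structure(list(sets = sets, classes = list()),
                     class = "overlap_decomposition"))
  }
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, nm))
  key <- apply(membership, 1, function(row) {
    paste(sort(nm[row]), collapse = "&")
  })
  classes <- split(universe, key)
  classes <- lapply(classes, sort)
  structure(list(sets = sets, classes = classes),
            class = "overlap_decomposition")
}

#' @export
print.overlap_decomposition <- function(x, ...) {
  cat("overlap_decomposition:", length(x$sets), "sets,",
      length(x$classes), "exclusive classes\n")
  if (length(x$classes)) {
    sizes <- vapply(x$classes, length, integer(1))
    print(sort(sizes, decreasing = TRUE))
  }
  if (!is.null(x$categories)) {
    cat("categories:\n")
    print(vapply(x$categories, function(cc) length(cc$genes), integer(1)))
  }
  invisible(x)
}

# category -> membership pattern over the four OPC comparisons
upset_category_patterns <- function() {
  cmp <- opc_comparisons()
  list(blue = cmp[1],                # KO-NS vs WT-NS only
       pink = cmp[4],                # KO-St vs WT-St only
       orange = cmp[3],              # KO-St vs KO-NS only
       gray = cmp[2],                # WT-St vs WT-NS only
       red = cmp[2:4])               # all three stimulation-involving sets
}

#' Label the named intersection categories of the four-comparison design
#'
#' Binds the five named categories to their membership patterns: the four
#' single-comparison classes (blue = genotype effect at baseline only,
#' gray = WT stimulation response only, orange = KO stimulation response
#' only, pink = genotype effect under stimulation only) and red = the class
#' of genes differentially expressed in all three stimulation-involving
#' comparisons. By default red uses exclusive UpSet semantics (the gene is
#' in exactly those three sets); `red_mode = "inclusive"` instead takes all
#' genes present in the three sets regardless of the fourth.
#'
#' @param decomposition An [upset_decompose()] result whose set names
#'   include all four [opc_comparisons()].
#' @param red_mode `"exclusive"` (default) or `"inclusive"`.
#' @return The decomposition with a `categories` element added: per
#'   category, the membership `pattern` and the `genes` it captures.
#' @export
label_categories <- function(decomposition,
                             red_mode = c("exclusive", "inclusive")) {
  red_mode <- match.arg(red_mode)
  if (!inherits(decomposition, "overlap_decomposition")) {
    stop("`decomposition` must come from upset_decompose()", call. = FALSE)
  }
  expected <- opc_comparisons()
  missing <- setdiff(expected, names(decomposition$sets))
  if (length(missing)) {
    stop("missing comparison set(s): ", paste(missing, collapse = ", "),
         "; expected all of: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  patterns <- upset_category_patterns()
  categories <- lapply(names(patterns), function(label) {
    pat <- patterns[[label]]
    if (label == "red" && red_mode == "inclusive") {
      genes <- Reduce(intersect, decomposition$sets[pat])
      genes <- sort(unique(genes))
    } else {
      key <- paste(sort(pat), collapse = "&")
      genes <- decomposition$classes[[key]]
      if (is.null(genes)) genes <- character()
    }
    list(pattern = pat, genes = genes)
  })
  names(categories) <- names(patterns)
  decomposition$categories <- categories
  decomposition$red_mode <- red_mode
  decomposition
}

#' Category size summary
#'
#' @param decomposition A labelled [label_categories()] decomposition.
#' @return Data frame with columns `category`, `pattern`, `size`.
#' @export
category_summary <- function(decomposition) {
  if (is.null(decomposition$categories)) {
    stop("run label_categories() first", call. = FALSE)
  }
  data.frame(
    category = names(decomposition$categories),
    pattern = vapply(decomposition$categories,
                     function(x) paste(x$pattern, collapse = "&"),
                     character(1)),
    size = vapply(decomposition$categories,
                  function(x) length(x$genes), integer(1)),
    row.names = NULL
  )
}
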