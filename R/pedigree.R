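#' Pedigree objects
#'
#' A pedigree is a data frame with one row per animal and columns `id`,
#' `sire`, `dam` (NA for unknown/founder parents), `generation`
#' (non-negative integer, parents strictly precede offspring),
#' `fullsib_family` (label of the nuclear family an animal was born into,
#' NA for founders) and `family` (label of the top-level group of mutually
#' related animals).  `as_pedigree()` validates an existing data frame and
#' attaches the class; validation checks referential integrity, generation
#' ordering and acyclicity.
#'
#' @param x data frame with at least columns `id`, `sire`, `dam`.  Missing
#'   `generation` is derived from parent depth; missing `fullsib_family`
#'   is reconstructed from shared (sire, dam) pairs; missing `family` is
#'   derived as connected components of the parent graph.
#' @return An object of class `pedigree` (a data frame).
#' @examples
#' ped <- as_pedigree(data.frame(id = c("s", "d", "kid"),
#'                               sire = c(NA, NA, "s"),
#'                               dam  = c(NA, NA, "d")))
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x)))
    stop("pedigree requires columns: ", paste(need, collapse = ", "))
  x$id   <- as.character(x$id)
  x$sire <- .na_label(as.character(x$sire))
  x$dam  <- .na_label(as.character(x$dam))
  if (anyDuplicated(x$id))
    stop("duplicated animal ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  for (p in c("sire", "dam")) {
    bad <- x$id[i <- which(!is.na(x[[p]]) & !(x[[p]] %in% x$id))]
    if (length(bad))
      stop("animals with missing referenced ", p, ": ",
           paste(bad, collapse = ", "), " (", p, " ",
           paste(x[[p]][i], collapse = ", "), " not in pedigree)")
  }
  self <- x$id == x$sire | x$id == x$dam
  self[is.na(self)] <- FALSE
  if (any(self))
    stop("cycle detected: animal listed as its own parent: ",
         paste(x$id[self], collapse = ", "))
  gen <- .pedigree_depth(x)  # errors on cycles
  if (is.null(x$generation)) x$generation <- gen
  x$generation <- as.integer(x$generation)
  founder <- is.na(x$sire) & is.na(x$dam)
  ip <- match(x$sire, x$id)
  im <- match(x$dam, x$id)
  ok <- founder |
    (ifelse(is.na(ip), -1L, x$generation[ip]) < x$generation &
     ifelse(is.na(im), -1L, x$generation[im]) < x$generation)
  if (!all(ok))
    stop("parents must precede offspring in generation order; offending ids: ",
         paste(x$id[!ok], collapse = ", "))
  if (is.null(x$fullsib_family)) {
    key <- ifelse(founder, NA_character_, paste(x$sire, x$dam, sep = "\r"))
    x$fullsib_family <- ifelse(is.na(key), NA_character_,
                               paste0("fs", match(key, unique(key[!is.na(key)]))))
  } else {
    x$fullsib_family <- .na_label(as.character(x$fullsib_family))
    key <- paste(x$sire, x$dam, sep = "\r")
    for (f in unique(stats::na.omit(x$fullsib_family))) {
      k <- unique(key[which(x$fullsib_family == f)])
      if (length(k) > 1L)
        stop("fullsib_family ", f, " maps to more than one (sire, dam) pair")
    }
  }
  if (is.null(x$family)) x$family <- .pedigree_components(x)
  x$family <- as.character(x$family)
  x <- x[order(x$generation, x$id), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("pedigree", "data.frame")
  x
}

.na_label <- function(v) {
  v[v %in% c("", "0", "NA", "UNKNOWN", "unknown", ".")] <- NA_character_
  v
}

## generation depth by iterative relaxation; cycle -> no fixpoint in n passes
.pedigree_depth <- function(x) {
  n <- nrow(x)
  ip <- match(x$sire, x$id)
  im <- match(x$dam, x$id)
  gen <- rep(0L, n)
  for (pass in seq_len(n + 1L)) {
    new <- pmax(ifelse(is.na(ip), -1L, gen[ip]),
                ifelse(is.na(im), -1L, gen[im])) + 1L
    new[is.na(ip) & is.na(im)] <- 0L
    if (all(new == gen)) return(gen)
    gen <- new
  }
  stop("cycle detected in pedigree: no consistent generation ordering ",
       "exists (check ids ", paste(utils::head(x$id, 5), collapse = ", "), " ...)")
}

## connected components of the undirected parent-offspring graph
.pedigree_components <- function(x) {
  n <- nrow(x)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) comp[ri] <<- rj }
  ip <- match(x$sire, x$id); im <- match(x$dam, x$id)
  for (i in seq_len(n)) {
    if (!is.na(ip[i])) union2(i, ip[i])
    if (!is.na(im[i])) union2(i, im[i])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  paste0("fam", match(roots, unique(roots)))
}

#' Read a pedigree from CSV
#'
#' The canonical on-disk format is a CSV with header columns `id`, `sire`,
#' `dam` and optionally `generation`, `fullsib_family`, `family`.  Unknown
#' parents may be coded as empty, `0`, `NA` or `UNKNOWN`.
#'
#' @param path file path.
#' @return A [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  names(x)[names(x) == "fullsib"] <- "fullsib_family"
  if (!is.null(x$generation) && all(x$generation == "")) x$generation <- NULL
  if (!is.null(x$generation)) x$generation <- as.integer(x$generation)
  as_pedigree(x)
}

#' Write a pedigree to CSV
#'
#' @param ped pedigree object.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  utils::write.csv(as.data.frame(ped)[, c("id", "sire", "dam", "generation",
                                          "fullsib_family", "family")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat("Pedigree: ", nrow(x), " animals, ", nf, " founders, ",
      length(unique(stats::na.omit(x$fullsib_family))), " full-sib families, ",
      length(unique(x$family)), " top-level families, ",
      max(x$generation) + 1L, " generations\n", sep = "")
  invisible(x)
}
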