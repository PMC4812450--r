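#' Read and validate a studbook pedigree
#'
#' Parses a studbook CSV with columns \code{id}, \code{sire}, \code{dam},
#' \code{birth_date} (and optionally \code{origin}). Unknown parents —
#' empty, \code{NA} or \code{"UNKNOWN"} — are normalised to \code{"WILD"},
#' the studbook convention for wild-caught founders; a parent id that never
#' appears as an individual is likewise treated as an unrecorded founder.
#' An individual with both parents \code{WILD} is a founder. The pedigree
#' must be acyclic (nobody is their own ancestor) and ids unique.
#'
#' @param path studbook CSV path, or a data.frame with the same columns
#' @return data.frame of class \code{pedigree}: \code{id}, \code{sire},
#'   \code{dam}, \code{birth_date}, \code{founder}, ordered so parents
#'   precede offspring
#' @export
read_studbook <- function(path) {
  ped <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("studbook needs columns id, sire, dam")
  if (!"birth_date" %in% names(ped)) ped$birth_date <- NA_character_
  ped$id <- as.character(ped$id)
  if (anyDuplicated(ped$id))
    stop("duplicate id: ", ped$id[duplicated(ped$id)][1])
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "" | toupper(p) %in% c("WILD", "UNKNOWN")] <- "WILD"
    p[!(p %in% ped$id) & p != "WILD"] <- "WILD"
    p
  }
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  ped$founder <- ped$sire == "WILD" & ped$dam == "WILD"
  # topological order; failure to make progress exposes a cycle
  placed <- character(0)
  remaining <- ped$id
  order_idx <- integer(0)
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(i) {
      k <- match(i, ped$id)
      all(c(ped$sire[k], ped$dam[k]) %in% c("WILD", placed))
    }, logical(1))
    if (!any(ready))
      stop("pedigree contains a cycle involving: ",
           paste(remaining, collapse = ", "))
    placed <- c(placed, remaining[ready])
    order_idx <- c(order_idx, match(remaining[ready], ped$id))
    remaining <- remaining[!ready]
  }
  out <- ped[order_idx, c("id", "sire", "dam", "birth_date", "founder")]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Kinship matrix and inbreeding coefficients by the tabular method
#'
#' Computes the kinship coefficient f(i, j) — the probability that one
#' allele drawn at random from each of i and j is identical by descent —
#' for every pair in the pedigree, by the recursive tabular method over the
#' parent-before-offspring ordering:
#' f(i, j) = (f(sire_i, j) + f(dam_i, j)) / 2 for j already placed, with
#' f involving an unknown (\code{WILD}) parent equal to 0, and
#' f(i, i) = (1 + F(i)) / 2. The inbreeding coefficient F(i) is the kinship
#' of i's parents. Founders are assumed unrelated and non-inbred — the
#' standard (and for wild-caught founders optimistic) studbook assumption,
#' which genomic autozygosity estimates can then be held against.
#'
#' @param ped a \code{pedigree} from \code{\link{read_studbook}}
#' @return list with \code{kinship}: symmetric matrix of f(i, j); and
#'   \code{F}: named vector of per-individual inbreeding coefficients
#' @export
kinship <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- read_studbook(ped)
  n <- nrow(ped)
  ids <- ped$id
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  Fv <- stats::setNames(numeric(n), ids)
  f_of <- function(a, b) {
    if (a == "WILD" || b == "WILD") 0 else K[a, b]
  }
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    Fv[i] <- f_of(s, d)
    K[i, i] <- (1 + Fv[i]) / 2
    if (i > 1) for (j in seq_len(i - 1)) {
      K[i, j] <- K[j, i] <- (f_of(s, ids[j]) + f_of(d, ids[j])) / 2
    }
  }
  list(kinship = K, F = Fv)
}

#' Per-individual inbreeding coefficients
#'
#' Convenience wrapper around \code{\link{kinship}} returning only F.
#'
#' @param ped a \code{pedigree} from \code{\link{read_studbook}}
#' @return named vector of inbreeding coefficients
#' @export
inbreeding <- function(ped) kinship(ped)$F

# studbook dates: ISO-8601; bare years use a mid-year (1 July) convention
parse_studbook_date <- function(x) {
  x <- as.character(x)
  x[grepl("^\\d{4}$", x)] <- paste0(x[grepl("^\\d{4}$", x)], "-07-01")
  as.Date(x)
}

#' Mean generation time of a pedigree
#'
#' The mean parental age at offspring birth, in years, over every
#' parent-offspring pair where both birth dates are known.
#'
#' @param ped a \code{pedigree} from \code{\link{read_studbook}}
#' @return generation time in years (double)
#' @export
generation_time <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- read_studbook(ped)
  bd <- stats::setNames(parse_studbook_date(ped$birth_date), ped$id)
  ages <- c()
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (p != "WILD" && !is.na(bd[p]) && !is.na(bd[ped$id[i]]))
        ages <- c(ages, as.numeric(bd[ped$id[i]] - bd[p]) / 365.25)
    }
  }
  if (length(ages) == 0L)
    stop("no parent-offspring pairs with known birth dates")
  mean(ages)
}
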