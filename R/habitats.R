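# Habitat and sampling-fraction tables.
#
# Habitat codes cross salinity with a merged bottom-association category:
#   RA  marine reef-associated        MD  marine demersal
#   MB  marine benthopelagic          MP  marine pelagic
#   FD  freshwater demersal           FB  freshwater benthopelagic
#   FP  freshwater pelagic

.habitat_vocab <- c("reef-associated", "demersal", "bathydemersal",
                    "benthopelagic", "pelagic", "bathypelagic",
                    "pelagic-oceanic", "pelagic-neritic")

.habitat_merge <- c(
  "reef-associated" = "reef-associated",
  "demersal"        = "demersal",
  "bathydemersal"   = "demersal",
  "benthopelagic"   = "benthopelagic",
  "pelagic"         = "pelagic",
  "bathypelagic"    = "pelagic",
  "pelagic-oceanic" = "pelagic",
  "pelagic-neritic" = "pelagic")

.habitat_code <- c(
  "marine.reef-associated"   = "RA",
  "marine.demersal"          = "MD",
  "marine.benthopelagic"     = "MB",
  "marine.pelagic"           = "MP",
  "freshwater.demersal"      = "FD",
  "freshwater.benthopelagic" = "FB",
  "freshwater.pelagic"       = "FP")

#' Read a species trait table
#'
#' Delimited text with a header row; the delimiter is auto-detected among
#' comma and tab.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_trait_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, strip.white = TRUE)
}

#' Resolve raw habitat records to the seven habitat codes
#'
#' Applies the classification rules: within each salinity class, demersal-type
#' categories (demersal, bathydemersal) merge to demersal and pelagic-type
#' categories (pelagic, bathypelagic, pelagic-oceanic, pelagic-neritic) merge
#' to pelagic; reef-associated is marine-only. Species recorded in more than
#' one salinity class (freshwater together with marine and/or brackish) are
#' excluded. Unknown habitat strings are flagged unresolvable rather than
#' dropped.
#'
#' @param table Data.frame with columns `species`, `salinity` and `habitat`.
#'   `salinity` is one of `"marine"`, `"freshwater"`, `"brackish"`, or a
#'   `+`-joined combination (e.g. `"freshwater+brackish"`). Reef association
#'   in fresh water has no code and is excluded.
#' @return The input with added columns `resolved_habitat` (one of the 7
#'   codes or `NA`) and `status` (`"ok"`, `"excluded"` or `"unresolvable"`).
#' @export
resolve_habitats <- function(table) {
  stopifnot(all(c("species", "salinity", "habitat") %in% names(table)))
  sal <- tolower(trimws(table$salinity))
  hab <- tolower(trimws(table$habitat))
  n <- nrow(table)
  resolved <- rep(NA_character_, n)
  status <- rep("excluded", n)

  sal_parts <- strsplit(sal, "+", fixed = TRUE)
  multi_sal <- vapply(sal_parts, function(p) length(unique(p)) > 1, logical(1))
  single_sal <- vapply(sal_parts, function(p) p[1], character(1))

  unknown <- !(hab %in% .habitat_vocab) |
    !(single_sal %in% c("marine", "freshwater", "brackish"))
  status[unknown] <- "unresolvable"

  ok <- !unknown & !multi_sal & single_sal %in% c("marine", "freshwater")
  key <- paste(single_sal[ok], .habitat_merge[hab[ok]], sep = ".")
  code <- unname(.habitat_code[key])
  resolved[ok][!is.na(code)] <- code[!is.na(code)]
  status[ok][!is.na(code)] <- "ok"

  table$resolved_habitat <- resolved
  table$status <- status
  table
}

#' Sampling fraction
#'
#' @param n_in_tree Number of species of the group present in the tree.
#' @param n_total Total described species in the group, or `NULL` to pass a
#'   fraction directly via `rho`.
#' @param rho Direct fraction when counts are not available.
#' @return An object of class `sampling_fraction` with elements `rho`,
#'   `n_in_tree`, `n_total`.
#' @export
sampling_fraction <- function(n_in_tree = NULL, n_total = NULL, rho = NULL) {
  if (is.null(rho)) {
    stopifnot(!is.null(n_in_tree), !is.null(n_total), n_total >= n_in_tree,
              n_in_tree > 0)
    rho <- n_in_tree / n_total
  }
  if (!(rho > 0 && rho <= 1)) stop("rho must be in (0, 1]")
  structure(list(rho = rho, n_in_tree = n_in_tree, n_total = n_total),
            class = "sampling_fraction")
}

as_rho <- function(x) {
  if (inherits(x, "sampling_fraction")) x$rho else {
    stopifnot(is.numeric(x), length(x) == 1, x > 0, x <= 1)
    as.numeric(x)
  }
}
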