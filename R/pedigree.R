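#' Construct a pedigree
#'
#' @param id character vector of individual ids.
#' @param sex "M"/"F" per individual.
#' @param mother,father parent ids or NA; an individual must have either both
#'   parents or neither (use unassayed placeholder founders for unknown
#'   parents, as real pedigrees do).
#' @param assayed logical; whether the individual is sequenced. Unassayed
#'   members still transmit haplotypes.
#' @return data.frame of class `pedigree` with a `founder` column.
#' @export
pedigree <- function(id, sex, mother = NA, father = NA, assayed = TRUE) {
  ped <- data.frame(id = as.character(id), sex = sex,
                    mother = as.character(mother), father = as.character(father),
                    assayed = assayed, stringsAsFactors = FALSE)
  ped$founder <- is.na(ped$mother) & is.na(ped$father)
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stopf("duplicated individual ids in pedigree")
  half <- xor(is.na(ped$mother), is.na(ped$father))
  if (any(half)) stopf("individuals must have both parents or none: %s",
                       paste(ped$id[half], collapse = ", "))
  for (col in c("mother", "father")) {
    missing <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(missing)) stopf("referenced parent not in pedigree: %s",
                            paste(unique(ped[[col]][missing]), collapse = ", "))
  }
  # Acyclic check by founder peeling; doubles as topological ordering.
  pedigree_order(ped)
  invisible(ped)
}

# Topological ordering (founders first); errors on cycles.
pedigree_order <- function(ped) {
  placed <- character(0)
  remaining <- ped$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$mother) || r$mother %in% placed) &&
        (is.na(r$father) || r$father %in% placed)
    }, logical(1))
    if (!any(ready)) stopf("pedigree contains a cycle involving: %s",
                           paste(remaining, collapse = ", "))
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' Default three-generation family pedigree
#'
#' Six assayed family members spanning three generations: two grandmothers
#' ("A" maternal-side, "B" paternal-side), the father "C" and mother "D", and
#' two sons "E" and "F", plus two assayed unrelated individuals "G" and "H".
#' The two grandfathers are present as unassayed placeholder founders so that
#' every non-founder has two parents.
#'
#' @return a `pedigree`.
#' @export
default_family_pedigree <- function() {
  pedigree(
    id      = c("A", "GF_A", "B", "GF_B", "C",    "D",    "E", "F", "G", "H"),
    sex     = c("F", "M",    "F", "M",    "M",    "F",    "M", "M", "M", "F"),
    mother  = c(NA,  NA,     NA,  NA,     "B",    "A",    "D", "D", NA,  NA),
    father  = c(NA,  NA,     NA,  NA,     "GF_B", "GF_A", "C", "C", NA,  NA),
    assayed = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Read/write PED-like pedigree tables
#'
#' Plain TSV with columns id, sex, mother, father, assayed; "0" or empty for
#' missing parents.
#'
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  fix <- function(x) ifelse(x %in% c("0", "", NA), NA, x)
  pedigree(df$id, df$sex, fix(df$mother), fix(df$father),
           assayed = if ("assayed" %in% names(df)) df$assayed %in% c("1", "TRUE", "yes") else TRUE)
}

#' @rdname read_pedigree
#' @param ped a `pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$mother[is.na(out$mother)] <- "0"
  out$father[is.na(out$father)] <- "0"
  out$assayed <- as.integer(out$assayed)
  write.table(out[, c("id", "sex", "mother", "father", "assayed")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
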