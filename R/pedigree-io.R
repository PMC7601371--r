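# PED-dialect pedigree I/O with a phenotype sidecar table.
#
# PED file: 6 whitespace-delimited columns (family, individual, father,
# mother, sex, affection), founder marker "0", sex coded 1/2/0. The
# affection column is written for interoperability (2/1/0 = affected /
# control / unphenotyped under the combined category) but ignored on
# input: the sidecar TSV is authoritative for phenotype.
#
# Sidecar TSV: header `id  phenotype  alive  age  goitre`, missing token
# "NA", UTF-8.

#' Read a cohort from PED + phenotype sidecar files
#'
#' @param ped_path Path to a 6-column PED file (family, individual,
#'   father, mother, sex, affection placeholder; founder marker `"0"`).
#' @param phenotype_path Path to the sidecar TSV keyed by individual id
#'   with columns `id`, `phenotype`, `alive`, `age`, `goitre`.
#' @return A validated [cohort()] object.
#' @export
read_pedigree <- function(ped_path, phenotype_path) {
  ped_cols <- c("family_id", "id", "father_id", "mother_id", "sex", "affection")
  ped <- tryCatch(
    utils::read.table(ped_path, header = FALSE, colClasses = "character",
                      col.names = ped_cols, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        as.data.frame(stats::setNames(rep(list(character(0)), 6L), ped_cols))
      } else {
        stop(e)
      }
    })
  sidecar <- utils::read.delim(phenotype_path, header = TRUE,
                               colClasses = "character",
                               na.strings = "NA", stringsAsFactors = FALSE)
  required <- c("id", "phenotype", "alive", "age", "goitre")
  if (!identical(names(sidecar), required)) {
    stop("phenotype sidecar must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(sidecar$id)) {
    stop("duplicate id(s) in phenotype sidecar: ",
         paste(unique(sidecar$id[duplicated(sidecar$id)]), collapse = ", "))
  }
  unknown <- setdiff(sidecar$id, ped$id)
  if (length(unknown) > 0L) {
    stop("phenotype sidecar references unknown individual(s): ",
         paste(unknown, collapse = ", "))
  }
  m <- match(ped$id, sidecar$id)
  if (anyNA(m)) {
    stop("individual(s) missing from phenotype sidecar: ",
         paste(ped$id[is.na(m)], collapse = ", "))
  }
  sidecar <- sidecar[m, , drop = FALSE]
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[ped$sex]
  if (anyNA(sex)) stop("invalid PED sex code(s): ",
                       paste(unique(ped$sex[is.na(sex)]), collapse = ", "))
  alive <- sidecar$alive %in% c("1", "TRUE", "true")
  cohort(data.frame(
    id = ped$id,
    family_id = ped$family_id,
    father_id = ifelse(ped$father_id == "0", NA_character_, ped$father_id),
    mother_id = ifelse(ped$mother_id == "0", NA_character_, ped$mother_id),
    sex = unname(sex),
    alive = alive,
    age_years = as.numeric(sidecar$age),
    phenotype = sidecar$phenotype,
    goitre = sidecar$goitre,
    stringsAsFactors = FALSE
  ))
}

#' Write a cohort to PED + phenotype sidecar files
#'
#' The inverse of [read_pedigree()]: files written here are read back to an
#' identical cohort. The PED affection column carries the combined-category
#' affection status (2 affected, 1 control, 0 unphenotyped); the sidecar is
#' the authoritative phenotype record.
#'
#' @param x An `ech_cohort`.
#' @inheritParams read_pedigree
#' @return Invisibly, `x`.
#' @export
write_pedigree <- function(x, ped_path, phenotype_path) {
  stopifnot(inherits(x, "ech_cohort"))
  ind <- x$individuals
  mask <- phenotype_mask(x, "combined")
  affection <- c(affected = "2", control = "1", unphenotyped = "0")[mask]
  ped <- data.frame(
    ind$family_id, ind$id,
    ifelse(is.na(ind$father_id), "0", ind$father_id),
    ifelse(is.na(ind$mother_id), "0", ind$mother_id),
    c(male = "1", female = "2", unknown = "0")[ind$sex],
    unname(affection)
  )
  utils::write.table(ped, ped_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- data.frame(
    id = ind$id,
    phenotype = ind$phenotype,
    alive = ifelse(ind$alive, "1", "0"),
    age = ind$age_years,
    goitre = ind$goitre
  )
  utils::write.table(sidecar, phenotype_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(x)
}
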