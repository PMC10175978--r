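#' Benzodiazepine and z-drug vocabulary
#'
#' Builds the drug vocabulary used to recognise benzodiazepine and z-drug
#' (BZD) prescriptions in free-text script items and to attach an elimination
#' half-life class to each generic. Long-acting means elimination half-life
#' greater than 24 hours (diazepam, nitrazepam, clonazepam, clobazam,
#' flunitrazepam); every other member of the class, including the z-drugs
#' zolpidem and zopiclone, is short-intermediate acting (half-life of 24 hours
#' or less). Common Australian brand names resolve to their generic.
#'
#' @param extra_synonyms optional named character vector mapping additional
#'   brand or spelling variants (names) to generic drug names (values).
#' @return An object of class \code{bzd_vocabulary}: a list with
#'   \code{generics} (data.frame of generic name and half-life class) and
#'   \code{synonyms} (named character vector, synonym -> generic).
#' @examples
#' v <- bzd_vocabulary()
#' is_bzd("Valium", v)
#' @export
bzd_vocabulary <- function(extra_synonyms = NULL) {
  long_acting <- c("diazepam", "nitrazepam", "clonazepam", "clobazam",
                   "flunitrazepam")
  short_intermediate <- c("temazepam", "oxazepam", "lorazepam", "bromazepam",
                          "alprazolam", "midazolam", "zolpidem", "zopiclone")
  generics <- data.frame(
    drug = c(long_acting, short_intermediate),
    half_life_class = rep(c("long_acting", "short_intermediate"),
                          c(length(long_acting), length(short_intermediate))),
    stringsAsFactors = FALSE
  )
  synonyms <- c(
    valium = "diazepam", antenex = "diazepam", ducene = "diazepam",
    mogadon = "nitrazepam", alodorm = "nitrazepam",
    rivotril = "clonazepam", paxam = "clonazepam",
    frisium = "clobazam",
    hypnodorm = "flunitrazepam",
    normison = "temazepam", temaze = "temazepam",
    serepax = "oxazepam", murelax = "oxazepam", alepam = "oxazepam",
    ativan = "lorazepam",
    lexotan = "bromazepam",
    xanax = "alprazolam", kalma = "alprazolam", alprax = "alprazolam",
    hypnovel = "midazolam",
    stilnox = "zolpidem", dormizol = "zolpidem",
    imovane = "zopiclone", imrest = "zopiclone"
  )
  if (!is.null(extra_synonyms)) {
    stopifnot(is.character(extra_synonyms), !is.null(names(extra_synonyms)))
    synonyms[tolower(names(extra_synonyms))] <- tolower(extra_synonyms)
  }
  structure(list(generics = generics, synonyms = synonyms),
            class = "bzd_vocabulary")
}

#' Read a BZD vocabulary from an editable JSON file
#'
#' The packaged vocabulary also ships as plain JSON
#' (\code{inst/extdata/bzd_vocabulary.json}) so deployments can add local
#' brand names or formulary quirks without touching code: the file carries
#' a \code{generics} table (drug, half-life class) and a \code{synonyms}
#' map (brand name to generic).
#'
#' @param path JSON file path; defaults to the copy shipped with the
#'   package.
#' @return A \code{bzd_vocabulary} object.
#' @examples
#' identical(bzd_vocabulary_from_json()$generics,
#'           bzd_vocabulary()$generics)
#' @export
bzd_vocabulary_from_json <- function(path = system.file(
  "extdata", "bzd_vocabulary.json", package = "bzdbp")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("generics", "synonyms") %in% names(raw)),
            all(c("drug", "half_life_class") %in% names(raw$generics)))
  syn <- unlist(raw$synonyms)
  structure(list(generics = as.data.frame(raw$generics),
                 synonyms = syn[sort(names(syn))]),
            class = "bzd_vocabulary")
}

#' Look up a drug name in the BZD vocabulary
#'
#' Case-folds the name, resolves brand-name synonyms to the generic, and
#' reports whether it is a benzodiazepine or z-drug and, if so, its half-life
#' class. Unknown drugs are simply not BZD; no error is raised.
#'
#' @param drug character vector of drug names (generic or brand, any case).
#' @param vocab a \code{\link{bzd_vocabulary}} object.
#' @return A data.frame with one row per input: \code{drug} (input),
#'   \code{generic} (resolved generic or \code{NA}), \code{is_bzd} (logical),
#'   \code{half_life_class} (\code{"long_acting"},
#'   \code{"short_intermediate"} or \code{NA}).
#' @examples
#' is_bzd(c("temazepam", "diazepam", "metformin"), bzd_vocabulary())
#' @export
is_bzd <- function(drug, vocab = bzd_vocabulary()) {
  stopifnot(inherits(vocab, "bzd_vocabulary"))
  key <- trimws(tolower(as.character(drug)))
  resolved <- ifelse(key %in% names(vocab$synonyms),
                     unname(vocab$synonyms[key]), key)
  idx <- match(resolved, vocab$generics$drug)
  data.frame(
    drug = as.character(drug),
    generic = ifelse(is.na(idx), NA_character_, vocab$generics$drug[idx]),
    is_bzd = !is.na(idx),
    half_life_class = ifelse(is.na(idx), NA_character_,
                             vocab$generics$half_life_class[idx]),
    stringsAsFactors = FALSE
  )
}
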