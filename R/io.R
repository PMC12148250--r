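#' @include AllClasses.R
NULL

## Long-format event tables: columns patient_id, date (ISO-8601), channel,
## value. CSV is the default interchange format; Parquet is available when
## the arrow package is installed.

#' Read / write long-format event tables
#'
#' @param path file path; `.parquet` files are handled through the arrow
#'   package, anything else as CSV.
#' @param events data.frame with columns `patient_id`, `date`, `channel`,
#'   `value`.
#' @return `readEventTable` returns a data.frame with those columns and
#'   `date` parsed as `Date`; `writeEventTable` returns `path` invisibly.
#' @export
readEventTable <- function(path) {
  ev <- if (grepl("\\.parquet$", path)) .readParquet(path)
        else as.data.frame(suppressWarnings(data.table::fread(
          path, colClasses = list(
            character = c("patient_id", "channel", "value")))))
  need <- c("patient_id", "date", "channel", "value")
  if (!all(need %in% names(ev)))
    stop("event table needs columns ", paste(need, collapse = ", "))
  ev$date <- as.Date(ev$date)
  ev$patient_id <- as.character(ev$patient_id)
  ev$value <- as.character(ev$value)
  ev[need]
}

#' @rdname readEventTable
#' @export
writeEventTable <- function(events, path) {
  events$date <- format(as.Date(events$date))
  if (grepl("\\.parquet$", path)) .writeParquet(events, path)
  else data.table::fwrite(events, path)
  invisible(path)
}

.readParquet <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("reading Parquet requires the arrow package")
  as.data.frame(arrow::read_parquet(path))
}
.writeParquet <- function(df, path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("writing Parquet requires the arrow package")
  arrow::write_parquet(df, path)
}

#' Read / write the demographics table
#'
#' @param path CSV with columns `patient_id`, `sex`, `birth_year`.
#' @param demo the corresponding data.frame.
#' @return `readDemographics` returns the data.frame.
#' @export
readDemographics <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("patient_id", "sex", "birth_year")
  if (!all(need %in% names(d)))
    stop("demographics table needs columns ", paste(need, collapse = ", "))
  d$patient_id <- as.character(d$patient_id)
  d[need]
}

#' @rdname readDemographics
#' @export
writeDemographics <- function(demo, path) {
  data.table::fwrite(demo, path)
  invisible(path)
}

#' Read / write a drug vocabulary CSV
#'
#' @param path CSV with columns `drug_id`, `drug_name`.
#' @param vocabulary a [DrugVocabulary-class].
#' @return `readDrugVocabulary` returns a [DrugVocabulary-class] ordered as
#'   in the file.
#' @export
readDrugVocabulary <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  if (!"drug_id" %in% names(d)) stop("vocabulary CSV needs a drug_id column")
  drugVocabulary(as.character(d$drug_id))
}

#' @rdname readDrugVocabulary
#' @export
writeDrugVocabulary <- function(vocabulary, path) {
  data.table::fwrite(data.frame(drug_id = vocabulary@drugs,
                                drug_name = vocabulary@drugs), path)
  invisible(path)
}

#' Assemble PatientHistory objects from long tables
#'
#' @param events long event table (see [readEventTable()]).
#' @param demographics demographics table (see [readDemographics()]).
#' @return Named list of [PatientHistory-class], one per patient in
#'   `demographics`.
#' @export
assembleHistories <- function(events, demographics) {
  ev <- split(events[c("date", "channel", "value")], events$patient_id)
  out <- lapply(seq_len(nrow(demographics)), function(i) {
    pid <- demographics$patient_id[i]
    e <- ev[[pid]]
    if (is.null(e)) e <- data.frame(date = as.Date(character(0)),
                                    channel = character(0), value = character(0))
    patientHistory(pid, demographics$sex[i], demographics$birth_year[i], e)
  })
  names(out) <- demographics$patient_id
  out
}

#' Flatten PatientHistory objects back to a long event table
#'
#' @param histories list of [PatientHistory-class].
#' @return data.frame with columns `patient_id`, `date`, `channel`, `value`.
#' @export
eventTable <- function(histories) {
  if (is(histories, "PatientHistory")) histories <- list(histories)
  do.call(rbind, lapply(histories, function(h) {
    if (nrow(h@events) == 0) return(NULL)
    data.frame(patient_id = h@patientId, h@events)
  }))
}

#' Serialize / read a prescriber policy as YAML
#'
#' @param policy a [PrescriberPolicy-class].
#' @param path YAML file.
#' @return `readPolicy` returns the [PrescriberPolicy-class].
#' @export
writePolicy <- function(policy, path) {
  yaml::write_yaml(list(noise_rate = policy@noiseRate,
                        rules = lapply(policy@rules, function(r) {
                          r$drugs <- as.list(r$drugs)
                          r
                        })), path)
  invisible(path)
}

#' @rdname writePolicy
#' @export
readPolicy <- function(path) {
  x <- yaml::read_yaml(path)
  rules <- lapply(x$rules, function(r)
    policyRule(r$id, r$channel, r$op, r$threshold,
               unlist(r$drugs), r$activeFrom %||% NA_integer_))
  prescriberPolicy(rules, x$noise_rate)
}
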