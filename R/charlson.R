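# Deyo ICD-9-CM adaptation of the Charlson comorbidity index:
# 17 condition categories, prefix-matched on dot-less codes.
deyo_map <- function() {
  list(
    mi            = list(w = 1L, p = c("410", "412")),
    chf           = list(w = 1L, p = "428"),
    pvd           = list(w = 1L, p = c("4439", "441", "7854", "V434")),
    cvd           = list(w = 1L, p = sprintf("43%d", 0:8)),
    dementia      = list(w = 1L, p = "290"),
    copd          = list(w = 1L, p = c(sprintf("49%d", 0:6),
                                       sprintf("50%d", 0:5), "5064")),
    rheum         = list(w = 1L, p = c("7100", "7101", "7104", "7140",
                                       "7141", "7142", "71481", "5172")),
    pud           = list(w = 1L, p = sprintf("53%d", 1:4)),
    mild_liver    = list(w = 1L, p = c("5712", "5714", "5715", "5716")),
    dm            = list(w = 1L, p = c(sprintf("250%d", 0:3), "2507")),
    dm_compl      = list(w = 2L, p = sprintf("250%d", 4:6)),
    plegia        = list(w = 2L, p = c("342", "3441")),
    renal         = list(w = 2L, p = c("582", sprintf("583%d", 0:7),
                                       "585", "586", "5880")),
    malignancy    = list(w = 2L, p = c(sprintf("1%02d", c(40:72, 74:95)),
                                       sprintf("20%d", 0:8))),
    severe_liver  = list(w = 3L, p = c(sprintf("456%d", 0:2),
                                       sprintf("572%d", 2:8))),
    mets          = list(w = 6L, p = sprintf("19%d", 6:9)),
    hiv           = list(w = 6L, p = c("042", "043", "044"))
  )
}

#' Charlson comorbidity index (Deyo ICD-9-CM adaptation)
#'
#' Scores a patient's baseline diagnoses over the 17 Deyo condition
#' categories with the standard weights (ten 1s; diabetes-with-
#' complications, hemiplegia, renal disease and malignancy at 2; moderate/
#' severe liver disease at 3; metastatic solid tumour and AIDS at 6).
#' A category counts once no matter how many claims carry it, and the
#' usual hierarchy rules apply: complicated diabetes supersedes
#' uncomplicated, severe liver disease supersedes mild, metastatic tumour
#' supersedes non-metastatic malignancy.
#'
#' @param codes character vector of diagnosis codes from the patient's
#'   baseline claims (all positions), dotted or dot-less.
#' @return non-negative integer score.
#' @export
#' @examples
#' charlson_score(character(0))            # 0
#' charlson_score("428.0")                 # 1 (CHF)
#' charlson_score(c("25001", "25040"))     # 2 (diabetes, complicated)
charlson_score <- function(codes) {
  codes <- norm_dx(codes[!is.na(codes) & nzchar(codes)])
  if (!length(codes)) return(0L)
  m <- deyo_map()
  hit <- vapply(m, function(cat) {
    any(vapply(cat$p, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  if (hit[["dm_compl"]]) hit[["dm"]] <- FALSE
  if (hit[["severe_liver"]]) hit[["mild_liver"]] <- FALSE
  if (hit[["mets"]]) hit[["malignancy"]] <- FALSE
  w <- vapply(m, `[[`, integer(1), "w")
  sum(w[hit])
}
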