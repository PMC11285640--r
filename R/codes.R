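#' Diagnosis code registry for MDD and AD
#'
#' The default registry implements the printed code lists: ICD-9-CM 296.2X
#' and ICD-10-CM F32.X for major depressive disorder (single episode, all
#' severities), and ICD-9-CM 331.0 with ICD-10-CM G30.0, G30.1, G30.8 and
#' G30.9 for Alzheimer's disease. MDD families are prefix-matched
#' (the "X" wildcard); AD codes are matched exactly. An extended registry
#' additionally accepts the recurrent-episode families 296.3X and F33.X;
#' the two registries are never merged silently.
#'
#' @param extended Logical; if `TRUE`, include recurrent-depression families.
#' @return A list with `mdd_prefix` (named by code system), `ad_exact`.
#' @export
code_registry <- function(extended = FALSE) {
  reg <- list(
    mdd_prefix = list(ICD9 = c("296.2"), ICD10 = c("F32")),
    ad_exact   = list(ICD9 = c("331.0"),
                      ICD10 = c("G30.0", "G30.1", "G30.8", "G30.9"))
  )
  if (extended) {
    reg$mdd_prefix$ICD9 <- c(reg$mdd_prefix$ICD9, "296.3")
    reg$mdd_prefix$ICD10 <- c(reg$mdd_prefix$ICD10, "F33")
  }
  reg
}

#' Classify a diagnosis code as MDD, AD or OTHER
#'
#' Vectorised over `code`. MDD families use prefix matching (so "296.21"
#' matches the 296.2X family); AD codes require an exact match.
#'
#' @param code_system `"ICD9"` or `"ICD10"` (recycled against `code`).
#' @param code Character vector of diagnosis codes.
#' @param registry A [code_registry()].
#' @return Character vector in `{"MDD","AD","OTHER"}`.
#' @examples
#' classify_code("ICD10", "G30.9")  # "AD"
#' classify_code("ICD9", "296.21")  # "MDD"
#' @export
classify_code <- function(code_system, code, registry = code_registry()) {
  if (length(code) == 0) return(character(0))
  if (any(!nzchar(code)) || any(is.na(code))) {
    stop("empty diagnosis code", call. = FALSE)
  }
  n <- max(length(code_system), length(code))
  code_system <- rep_len(code_system, n)
  code <- rep_len(code, n)
  bad <- !code_system %in% c("ICD9", "ICD10")
  if (any(bad)) {
    stop(sprintf("unknown code system: %s",
                 paste(unique(code_system[bad]), collapse = ", ")),
         call. = FALSE)
  }
  out <- rep("OTHER", n)
  for (sys in c("ICD9", "ICD10")) {
    i <- code_system == sys
    if (!any(i)) next
    is_mdd <- rep(FALSE, sum(i))
    for (pre in registry$mdd_prefix[[sys]]) {
      is_mdd <- is_mdd | startsWith(code[i], pre)
    }
    out[i][is_mdd] <- "MDD"
    out[i][code[i] %in% registry$ad_exact[[sys]]] <- "AD"
  }
  out
}

# code system implied by calendar year (ICD-10 switch in 2016)
code_system_for_year <- function(year) ifelse(year <= 2015, "ICD9", "ICD10")
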