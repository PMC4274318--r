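## XPLOR-style energy reporting.
##
## Bonded terms (BOND/ANGL/DIHE/IMPR) are reported as 0.000: the bodies are
## rigid and no bonded force field is evaluated here, whereas a full
## treatment would inherit those terms from the starting coordinates.

fmt3 <- function(x) sprintf("%.3f", x)

#' Format an energy breakdown as a pipe-delimited block
#'
#' Three lines listing Etotal, grad(E) and every term to 3 decimals, in the
#' customary layout.
#'
#' @param e an `energy_breakdown`.
#' @return character vector of lines.
#' @export
format_energy_block <- function(e) {
  t <- e$terms
  c(
    sprintf("| Etotal =%s grad(E)=%s E(BOND)=%s E(ANGL)=%s |",
            fmt3(e$Etotal), fmt3(e$grad), fmt3(t[["BOND"]]), fmt3(t[["ANGL"]])),
    sprintf("| E(DIHE)=%s E(IMPR)=%s E(VDW)=%s E(ELEC)=%s |",
            fmt3(t[["DIHE"]]), fmt3(t[["IMPR"]]), fmt3(t[["VDW"]]),
            fmt3(t[["ELEC"]])),
    sprintf("| E(NCS)=%s E(NOE)=%s |", fmt3(t[["NCS"]]), fmt3(t[["NOE"]]))
  )
}

#' Format NOE restraint rows
#'
#' Header with the class parameters, one line per restraint with the
#' ensemble-averaged distance, target, bounds, signed delta and energy,
#' then the RMS / violation summary line.
#'
#' @param rows list of `restraint_row`.
#' @param params a `restraint_params`.
#' @param class_name restraint class label (default `"EPR"`).
#' @return character vector of lines.
#' @export
format_noe_rows <- function(rows, params = restraint_params(),
                            class_name = "EPR") {
  out <- c(
    sprintf("++++++++++++ CLASS %s ++++++++++++++", class_name),
    sprintf("for this class: SCALe=%s AVERage=%s POTEntial=square-well",
            fmt3(params$scale), params$averaging)
  )
  for (r in rows) {
    out <- c(out, sprintf(
      "R<average> = %s NOE = %.2f (-%.2f/+%.2f) Delta = %s E(NOE)= %s",
      fmt3(r$r_average), r$d_target, r$d_minus, r$d_plus,
      fmt3(r$delta), fmt3(r$energy)))
  }
  if (length(rows) == 0) {
    out <- c(out, "NOEPRI: RMS diff. = 0.000, #(violat.> 0.0)= 0 of 0 NOEs")
  } else {
    sm <- noe_summary(rows)
    out <- c(out, sprintf(
      "NOEPRI: RMS diff. = %s, #(violat.> 0.0)= %d of %d NOEs",
      fmt3(sm$rms), sm$n_violated, sm$n))
  }
  out
}

breakdown_to_list <- function(e) {
  list(Etotal = e$Etotal, grad = e$grad, terms = as.list(e$terms),
       noe_rows = lapply(e$noe_rows, function(r) {
         list(r_average = r$r_average, target = r$d_target,
              minus = r$d_minus, plus = r$d_plus,
              delta = r$delta, energy = r$energy)
       }))
}

list_to_breakdown <- function(l) {
  rows <- lapply(l$noe_rows, function(r) {
    structure(list(r_average = r$r_average, d_target = r$target,
                   d_minus = r$minus, d_plus = r$plus,
                   delta = r$delta, energy = r$energy, dEdr = 0, label = ""),
              class = "restraint_row")
  })
  structure(list(Etotal = l$Etotal, grad = l$grad,
                 terms = unlist(l$terms), noe_rows = rows),
            class = "energy_breakdown")
}

#' Build a run report
#'
#' Serialisable record of a staged run: pre/post energy breakdowns per
#' stage, the final NOE rows with their summary, and the output file
#' manifest. Round-trips losslessly through JSON, and its text rendering is
#' byte-stable for identical reports.
#'
#' @param stage_results named list of per-stage results (as produced by
#'   [run_staged_protocol()]).
#' @param params a `restraint_params`.
#' @param files output file manifest.
#' @return a `run_report`.
#' @export
run_report <- function(stage_results, params = restraint_params(),
                       files = character(0)) {
  structure(list(
    stages = lapply(stage_results, function(st) {
      list(name = st$name, pre = breakdown_to_list(st$pre),
           post = breakdown_to_list(st$post),
           n_accepted = max(0L, length(st$trace) - 1L))
    }),
    params = list(scale = params$scale, averaging = params$averaging,
                  potential = params$potential,
                  sqconstant = params$sqconstant,
                  sqexponent = params$sqexponent, ceiling = params$ceiling),
    manifest = as.character(files)),
    class = "run_report")
}

#' Render a run report as fixed-format text
#'
#' @param report a `run_report`.
#' @return character vector of lines.
#' @export
format_run_report <- function(report) {
  out <- character(0)
  for (st in report$stages) {
    out <- c(out, sprintf("==== stage %s ====", st$name),
             "Before minimisation:",
             format_energy_block(list_to_breakdown(st$pre)),
             "After minimisation:",
             format_energy_block(list_to_breakdown(st$post)))
  }
  last <- report$stages[[length(report$stages)]]
  rows <- list_to_breakdown(last$post)$noe_rows
  prm <- restraint_params(averaging = report$params$averaging,
                          sqconstant = report$params$sqconstant,
                          sqexponent = report$params$sqexponent,
                          ceiling = report$params$ceiling,
                          scale = report$params$scale)
  c(out, "NOE energy breakdown:", format_noe_rows(rows, prm))
}

#' Write a run report as JSON
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run report from JSON
#' @param path JSON file written by [write_run_report()].
#' @return a `run_report`.
#' @export
read_run_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "run_report")
}
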