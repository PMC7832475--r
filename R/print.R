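#' @export
print.PatientReport <- function(x, ...) {
  cat(sprintf("Opportunistic BMD screening report: %s\n", x$id))
  for (m in x$measurements) {
    if (m$qc$included)
      cat(sprintf("  %s: mean %.1f HU over %d voxels -> %.1f mg/cm^3 (%s)\n",
                  m$level, m$mean_hu, m$n_voxels, m$bmd, m$category))
    else
      cat(sprintf("  %s: excluded (%s)\n", m$level,
                  paste(m$qc$reasons, collapse = ", ")))
  }
  cat(sprintf("  patient BMD %.1f mg/cm^3 (%s), levels %s\n",
              x$patient_bmd, x$patient_category,
              paste(x$levels_used, collapse = ",")))
  invisible(x)
}

#' @export
print.StatsReport <- function(x, ...) {
  cat("Case-control BMD analysis\n")
  g <- x$groups
  for (i in 1:2)
    cat(sprintf("  %-7s n=%d, BMD %.1f (%.1f) mg/cm^3\n",
                g$group[i], g$n[i], g$mean_bmd[i], g$sd_bmd[i]))
  cat(sprintf("  t-test: t = %.2f, df = %.1f, p = %.3f (%s variance)\n",
              x$t_test$t, x$t_test$df, x$t_test$p,
              if (x$t_test$equal_var_assumed) "pooled" else "Welch"))
  cat("  ACR category counts (case/control):\n")
  for (cc in rownames(x$categories)) {
    pchr <- if (!is.null(x$chi_square[[cc]]))
      sprintf("chi-square p = %.3f", x$chi_square[[cc]]$p) else "p n/a"
    cat(sprintf("    %-13s %d / %d  (%s)\n", cc,
                x$categories[cc, "case"], x$categories[cc, "control"], pchr))
  }
  cat(sprintf("  ROC: AUC = %.3f (95%% CI %.3f-%.3f), p = %.3f vs 0.5\n",
              x$roc$auc, x$roc$ci95[1], x$roc$ci95[2], x$roc$p_vs_half))
  cat(sprintf("  Youden point: BMD < %.1f, sens %.3f, spec %.3f, J = %.3f\n",
              x$youden$threshold, x$youden$sensitivity,
              x$youden$specificity, x$youden$youden_j))
  invisible(x)
}
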