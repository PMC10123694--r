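#!/usr/bin/env Rscript
# Stage 5: pooled fitness classification and agreement.
#
# Classifies observed isoinertial VO2max (the reference) and each
# refitted model's predictions into pooled poor/fair/good categories,
# then computes sensitivity, specificity (on the binary pooling
# positive = fair+good vs poor) and Cohen's kappa (on all three
# categories). Thresholds come from the packaged synthetic default
# table. Writes results/agreement.csv.

suppressPackageStartupMessages(library(isoruffier))

cohort <- read_cohort("results/cohort.csv")
fits <- fit_study_models(cohort)
thresholds <- default_crf_thresholds()

reference <- classify_crf(cohort$vo2max_iso, cohort$gender, thresholds)

agreement <- do.call(rbind, lapply(names(fits), function(nm) {
  pred_vals <- fits[[nm]]$loocv$per_fold  # held-out predictions
  predicted <- classify_crf(pred_vals, cohort$gender, thresholds)
  cm <- confusion_from_pairs(reference, predicted)
  agr <- agreement_from_confusion(cm)
  data.frame(model = nm, tpc = cm[["tpc"]], fnc = cm[["fnc"]],
             tnc = cm[["tnc"]], fpc = cm[["fpc"]],
             sensitivity = round_half_up(agr[["sensitivity"]], 3),
             specificity = round_half_up(agr[["specificity"]], 3),
             kappa = round_half_up(cohen_kappa(reference, predicted), 3))
}))
write.csv(agreement, "results/agreement.csv", row.names = FALSE)

message("Agreement between observed and model-predicted fitness categories")
message("(held-out predictions; synthetic default thresholds):")
print(agreement, row.names = FALSE)
message("Written to results/agreement.csv")
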