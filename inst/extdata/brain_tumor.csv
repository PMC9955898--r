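# Published evaluation of nine ML brain-tumor classifiers on six criteria.
# Cells store the published raw value and the published linguistic term
# verbatim, including the cells whose term contradicts the percentage
# banding rule; validate_labels() audits those.
#aim,max,max,max,min,max,max
#weight,VH,VH,H,H,H,VH
#pf,gaussian,gaussian,gaussian,gaussian,gaussian,gaussian
alternative,accuracy,precision,recall,processing_time,sensitivity,specificity
SVM,94.1|H,90.9|H,91|H,429|M,95.02|H,93.99|H
RF,96.4|VH,96|VH,90|H,412|M,89.89|M,95.23|H
GBM,96|VH,90|H,90|H,405|M,90.1|H,88.21|M
CNN,99.9|VH,100|VH,99|VH,301|L,95|H,98.13|VH
KNN,90.88|H,90.11|H,90|H,381|M,90.16|H,90.12|H
AlexNet,86|M,84|M,89|M,348|L,90.09|H,90.8|H
GoogLeNet,98|VH,95.78|H,94.1|H,322|L,94.8|H,97.12|VH
CNN VGG19,99|VH,90.5|H,99.1|VH,311|L,95.2|H,94.69|VH
CapsNet,96.56|VH,84.61|M,86|M,372|M,81.01|M,90.1|H
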