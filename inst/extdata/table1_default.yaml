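# Printed sex-by-status group statistics of the source cohort:
# analyte cells are [mean, SEM]; SDs are reconstructed as SEM * sqrt(n).
# BA carries no printed cells; it is drawn uninformatively (mean/SD given
# directly) within the instrument range.
rho_tp_alb: 0.3
vet_score:
  p_geom: 0.4
truncation: none
ba: {mean: 80.0, sd: 25.0}
groups:
  male_healthy:
    sex: male
    status: healthy
    "n": 9
    analytes:
      AST: [75, 22]
      CK: [1258, 500]
      GLU: [43, 7]
      Ca: [14.5, 0.2]
      PHOS: [8.0, 0.4]
      TP: [3.9, 0.1]
      ALB: [2.1, 0.1]
      K: [4.3, 0.2]
      Na: [172, 2]
    morpho: {total_length: 39.4, weight: 1.5, age: 5.5}
  male_diseased:
    sex: male
    status: diseased
    "n": 10
    analytes:
      AST: [64, 18]
      CK: [2123, 450]
      GLU: [32, 2]
      Ca: [12.2, 0.3]
      PHOS: [5.1, 0.3]
      TP: [3.1, 0.1]
      ALB: [1.6, 0.1]
      K: [4.1, 0.2]
      Na: [162, 3]
    morpho: {total_length: 43.3, weight: 2.0, age: 7.5}
  female_healthy:
    sex: female
    status: healthy
    "n": 9
    analytes:
      AST: [115, 47]
      CK: [2203, 680]
      GLU: [34, 2]
      Ca: [15.9, 0.6]
      PHOS: [7.6, 0.5]
      TP: [4.0, 0.2]
      ALB: [2.2, 0.1]
      K: [4.4, 0.3]
      Na: [170, 2]
    morpho: {total_length: 39.4, weight: 1.3, age: 6.4}
  female_diseased:
    sex: female
    status: diseased
    "n": 11
    analytes:
      AST: [61, 15]
      CK: [2079, 420]
      GLU: [36, 4]
      Ca: [14.8, 0.7]
      PHOS: [6.4, 0.4]
      TP: [3.3, 0.1]
      ALB: [2.0, 0.1]
      K: [4.1, 0.1]
      Na: [166, 3]
    morpho: {total_length: 41.8, weight: 1.5, age: 9.6}
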