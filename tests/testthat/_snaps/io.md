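# rendered reports are deterministic and complete for a seeded cohort

    Code
      writeLines(readLines(file.path(dir, "correlation_table.csv")))
    Output
      score,pwsy,weaned_piglet_cost,adg,fcr,medication_cost,postweaning_mortality,total_cost,cost_per_kg
      preweaning,0.07,-0.38,-0.38,-0.31,-0.01,-0.02,-0.31,-0.19
      batch,0.42 *,-0.31,-0.24,-0.33,-0.13,-0.09,-0.29,-0.51 *
      biosecurity,0.37,-0.43 *,0.23,-0.21,0.12,-0.17,-0.10,-0.04
      water,0.14,-0.25,-0.08,-0.31,0.05,-0.18,-0.15,-0.08
      feeding,0.39,-0.60 **,-0.34,-0.27,-0.12,-0.19,-0.14,-0.30
      health,0.24,-0.54 **,-0.17,-0.58 **,-0.03,-0.07,0.24,0.15
      training,0.01,-0.08,-0.11,-0.36,0.01,-0.17,0.15,-0.37
      temperature,0.24,-0.41,-0.35,-0.36,-0.18,-0.06,-0.31,-0.19
      ventilation,0.38,-0.59 **,-0.22,-0.61 **,-0.29,-0.08,-0.24,-0.13
      floor,0.52 *,-0.42 *,-0.12,-0.53 **,0.09,-0.09,-0.19,-0.19
      overall,0.49 *,-0.71 ***,-0.32,-0.67 ***,-0.07,-0.22,-0.22,-0.37

---

    Code
      writeLines(readLines(file.path(dir, "groups_by_pwsy.csv")))
    Output
      variable,Q1,Q2Q3,Q4,Total
      overall,57.77 (9.72),53.63 (9.72),47.94 (13.92),53.22 (11.04)
      sows,995.52 a (389.23),507.27 b (358.26),692.43 ab (226.22),682.94 (382.76)
      pwsy,28.55 a (1.39),25.06 b (0.69),21.76 c (1.74),25.11 (2.76)
      preweaning_mortality,9.87 (3.34),8.14 (3.61),10.58 (2.62),9.23 (3.35)
      weaning_weight,5.59 (0.21),5.77 (0.19),5.72 (0.11),5.71 (0.19)
      weaned_piglet_cost,24.69 (6.40),25.05 (3.35),28.55 (3.15),25.87 (4.40)
      adg,321.59 (21.51),330.11 (37.95),302.12 (33.34),320.59 (33.93)
      fcr,1.76 (0.19),1.73 (0.15),1.83 (0.24),1.76 (0.18)
      medication_cost,5.46 (1.84),5.46 (0.93),5.87 (1.39),5.57 (1.28)
      postweaning_mortality,3.52 (1.27),3.66 (1.46),3.02 (1.12),3.46 (1.30)
      total_cost,43.46 (4.39),45.59 (4.91),44.31 (7.50),44.70 (5.39)
      cost_per_kg,2.28 (0.31),2.35 (0.31),2.31 (0.28),2.32 (0.29)

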