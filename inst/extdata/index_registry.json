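[
  {"name": "England and Fraser (E&F)", "expression": "mcv - rbc - 5 * hb - 3.4", "cutoffs": [0], "btt_side": "below", "source": "England & Fraser 1973"},
  {"name": "RBC", "expression": "rbc", "cutoffs": [5], "btt_side": "above", "source": "Klee 1976; RBC count convention"},
  {"name": "Mentzer", "expression": "mcv / rbc", "cutoffs": [13], "btt_side": "below", "source": "Mentzer 1973"},
  {"name": "Srivastava", "expression": "mch / rbc", "cutoffs": [3.8], "btt_side": "below", "source": "Srivastava & Bevington 1973"},
  {"name": "Shine and Lal (S&L)", "expression": "mcv * mcv * mch / 100", "cutoffs": [1530], "btt_side": "below", "source": "Shine & Lal 1977"},
  {"name": "Bessman (RDW)", "expression": "rdw", "cutoffs": [14], "btt_side": "below", "source": "Bessman & Feinstein 1979"},
  {"name": "Ricerca", "expression": "rdw / rbc", "cutoffs": [4.4], "btt_side": "below", "source": "Ricerca 1987"},
  {"name": "Green and King (G&K)", "expression": "mcv * mcv * rdw / (100 * hb)", "cutoffs": [65], "btt_side": "below", "source": "Green & King 1989"},
  {"name": "Das Gupta", "expression": "1.89 * rbc - 0.33 * rdw - 3.28", "cutoffs": [0], "btt_side": "above", "source": "Das Gupta 1994"},
  {"name": "Jayabose (RDWI)", "expression": "mcv * rdw / rbc", "cutoffs": [220], "btt_side": "below", "source": "Jayabose 1999"},
  {"name": "Telmissani—MCHD", "expression": "mch / mcv", "cutoffs": [3.8], "btt_side": "below", "source": "Telmissani 1999; cutoff as commonly tabulated"},
  {"name": "Telmissani—MDHL", "expression": "mch * rbc / mcv", "cutoffs": [1.75], "btt_side": "above", "source": "Telmissani 1999"},
  {"name": "Huber—Herklotz", "expression": "mch * rdw / (10 * rbc) + rdw", "cutoffs": [20], "btt_side": "below", "source": "Huber/Herklotz 2004"},
  {"name": "Kerman I", "expression": "mcv * mch / rbc", "cutoffs": [300], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Kerman II", "expression": "mcv * mch * 10 / (rbc * mchc)", "cutoffs": [95], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Sirdah", "expression": "mcv - rbc - 3 * hb", "cutoffs": [27], "btt_side": "below", "source": "Sirdah 2007"},
  {"name": "Ehsani", "expression": "mcv - 10 * rbc", "cutoffs": [15], "btt_side": "below", "source": "Ehsani 2009"},
  {"name": "Bordbar", "expression": "abs(80 - mcv) * abs(27 - mch)", "cutoffs": [44.76], "btt_side": "above", "source": "Bordbar 2015"},
  {"name": "Matos and Carvalho", "expression": "1.91 * rbc + 0.44 * mchc", "cutoffs": [23.85], "btt_side": "above", "source": "Matos & Carvalho 2016"},
  {"name": "Janel (11 T)", "expression": "(mcv - rbc - 5 * hb - 3.4 < 0) + (rbc > 5) + (mcv / rbc < 13) + (mch / rbc < 3.8) + (mcv * mcv * mch / 100 < 1530) + (rdw < 14) + (rdw / rbc < 4.4) + (mcv * mcv * rdw / (100 * hb) < 65) + (1.89 * rbc - 0.33 * rdw - 3.28 > 0) + (mcv * rdw / rbc < 220) + (mcv - 10 * rbc < 15)", "cutoffs": [5.5], "btt_side": "above", "source": "Janel 2011 eleven-test vote; vote set reconstructed"},
  {"name": "CRUISE Index", "expression": "mcv + hb - mchc", "cutoffs": [46], "btt_side": "below", "source": "reconstructed from the CRUISE split variables (MCV, Hb, MCHC)"},
  {"name": "Index26", "expression": "mcv * mch / (rbc * hb)", "cutoffs": [28], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Hisham", "expression": "mcv * rdw / (10 * rbc)", "cutoffs": [22], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Hameed", "expression": "hb + mcv - rdw", "cutoffs": [61], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Ravanbakhsh-F1", "expression": "mcv / rbc + rdw", "cutoffs": [30], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Ravanbakhsh-F2", "expression": "mch / rbc + rdw", "cutoffs": [20.5], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Ravanbakhsh-F3", "expression": "mcv / rbc - hb", "cutoffs": [3.3], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Ravanbakhsh-F4", "expression": "mch / rbc - hb", "cutoffs": [-5.9], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Zaghloul1", "expression": "mchc * rdw / rbc", "cutoffs": [100], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Zaghloul2", "expression": "mch * mchc / rbc", "cutoffs": [132], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Kandhrol1", "expression": "hb * rbc / rdw", "cutoffs": [3.25], "btt_side": "above", "source": "reconstructed; primary formula unavailable"},
  {"name": "Kandhrol2", "expression": "mcv * hb / rbc", "cutoffs": [136], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Alparslan", "expression": "rdw * hb / rbc", "cutoffs": [33], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Merdin1", "expression": "mcv * rbc / rdw", "cutoffs": [21], "btt_side": "above", "source": "reconstructed; primary formula unavailable"},
  {"name": "Merdin2", "expression": "mch * rbc / rdw", "cutoffs": [6.7], "btt_side": "above", "source": "reconstructed; primary formula unavailable"},
  {"name": "Roth", "expression": "mcv * mcv * mch / (100 * rbc)", "cutoffs": [200], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Sargolzaie", "expression": "rbc * mchc / rdw", "cutoffs": [9.7], "btt_side": "above", "source": "reconstructed; primary formula unavailable"},
  {"name": "Keikhaei", "expression": "100 * hb * rdw / (rbc * rbc * mchc)", "cutoffs": [21], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Nishad", "expression": "0.615 * mcv + 0.518 * mch + 0.446 * rdw", "cutoffs": [59], "btt_side": "below", "source": "Nishad 2012; coefficients as commonly tabulated"},
  {"name": "Wongprachum", "expression": "mch * rdw / rbc", "cutoffs": [70], "btt_side": "below", "source": "reconstructed; primary formula unavailable"},
  {"name": "Sehgal", "expression": "mcv * mcv / rbc", "cutoffs": [972], "btt_side": "below", "source": "Sehgal 2015"},
  {"name": "Pornprasert (MCHC)", "expression": "mchc", "cutoffs": [31], "btt_side": "above", "source": "Pornprasert 2014"},
  {"name": "Sirachainan", "expression": "1.5 * hb - 0.05 * mcv", "cutoffs": [14], "btt_side": "above", "source": "Sirachainan 2014"}
]
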