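9	16420000	16434000	faire_peak_01	ovarian_surface_epithelium
9	16452000	16457000	h3k27ac_peak_01	ovarian_surface_epithelium
9	16488000	16503000	faire_peak_02	fallopian_tube_epithelium
9	16530000	16533500	h3k4me1_peak_01	ovarian_surface_epithelium
9	16561000	16579000	faire_peak_03	ovarian_surface_epithelium
9	16600000	16612000	h3k27ac_peak_02	fallopian_tube_epithelium
9	16648000	16652000	faire_peak_04	fallopian_tube_epithelium
9	16689000	16707000	h3k4me1_peak_02	ovarian_surface_epithelium
9	16701000	16719000	faire_peak_05	fallopian_tube_epithelium
9	16760000	16772000	h3k27ac_peak_03	ovarian_surface_epithelium
9	16801000	16808000	faire_peak_06	ovarian_surface_epithelium
9	16845000	16862000	h3k4me1_peak_03	fallopian_tube_epithelium
9	16888000	16896000	faire_peak_07	ovarian_surface_epithelium
9	16910000	16921000	h3k27ac_peak_04	fallopian_tube_epithelium
9	16955000	16968000	faire_peak_08	ovarian_surface_epithelium
9	17002000	17015000	h3k4me1_peak_04	ovarian_surface_epithelium
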