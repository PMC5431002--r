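animal_id,experiment_id,injection_type,onset_s
epileptic01,epileptic01_d01_KCl,KCl,-9000
epileptic01,epileptic01_d01_KCl,KCl,-5400
epileptic01,epileptic01_d01_KCl,KCl,-1800
epileptic01,epileptic01_d01_KCl,KCl,900
epileptic01,epileptic01_d01_KCl,KCl,2700
epileptic01,epileptic01_d01_KCl,KCl,4500
epileptic01,epileptic01_d01_KCl,KCl,6300
epileptic01,epileptic01_d01_KCl,KCl,8100
epileptic01,epileptic01_d01_KCl,KCl,9900
epileptic01,epileptic01_d12_KCl,KCl,-8100
epileptic01,epileptic01_d12_KCl,KCl,-2700
epileptic01,epileptic01_d12_KCl,KCl,2700
epileptic01,epileptic01_d12_KCl,KCl,8100
epileptic01,epileptic01_d21_KCl,KCl,-5400
epileptic01,epileptic01_d21_KCl,KCl,5400
epileptic02,epileptic02_d01_KCl,KCl,
epileptic03,epileptic03_d01_KCl,KCl,
epileptic03,epileptic03_d12_KCl,KCl,
epileptic03,epileptic03_d30_KCl,KCl,-5400
epileptic03,epileptic03_d30_KCl,KCl,1350
epileptic03,epileptic03_d30_KCl,KCl,4050
epileptic03,epileptic03_d30_KCl,KCl,6750
epileptic03,epileptic03_d30_KCl,KCl,9450
epileptic04,epileptic04_d01_KCl,KCl,-5400
epileptic04,epileptic04_d01_KCl,KCl,1350
epileptic04,epileptic04_d01_KCl,KCl,4050
epileptic04,epileptic04_d01_KCl,KCl,6750
epileptic04,epileptic04_d01_KCl,KCl,9450
epileptic04,epileptic04_d20_KCl,KCl,-5400.0000
epileptic04,epileptic04_d20_KCl,KCl,771.4286
epileptic04,epileptic04_d20_KCl,KCl,2314.2857
epileptic04,epileptic04_d20_KCl,KCl,3857.1429
epileptic04,epileptic04_d20_KCl,KCl,5400.0000
epileptic04,epileptic04_d20_KCl,KCl,6942.8571
epileptic04,epileptic04_d20_KCl,KCl,8485.7143
epileptic04,epileptic04_d20_KCl,KCl,10028.5714
epileptic04,epileptic04_d31_KCl,KCl,-5400
epileptic05,epileptic05_d01_KCl,KCl,-5400
epileptic05,epileptic05_d01_KCl,KCl,2700
epileptic05,epileptic05_d01_KCl,KCl,8100
epileptic05,epileptic05_d22_KCl,KCl,-5400
epileptic05,epileptic05_d22_KCl,KCl,2700
epileptic05,epileptic05_d22_KCl,KCl,8100
epileptic05,epileptic05_d30_KCl,KCl,-5400
epileptic05,epileptic05_d30_KCl,KCl,2700
epileptic05,epileptic05_d30_KCl,KCl,8100
epileptic06,epileptic06_d01_KCl,KCl,2700
epileptic06,epileptic06_d01_KCl,KCl,8100
epileptic06,epileptic06_d21_PBS,PBS,
epileptic07,epileptic07_d01_PBS,PBS,
epileptic07,epileptic07_d21_KCl,KCl,
epileptic08,epileptic08_d01_KCl,KCl,2700
epileptic08,epileptic08_d01_KCl,KCl,8100
epileptic08,epileptic08_d05_PBS,PBS,
epileptic09,epileptic09_d01_KCl,KCl,-9450
epileptic09,epileptic09_d01_KCl,KCl,-6750
epileptic09,epileptic09_d01_KCl,KCl,-4050
epileptic09,epileptic09_d01_KCl,KCl,-1350
epileptic09,epileptic09_d01_KCl,KCl,1800
epileptic09,epileptic09_d01_KCl,KCl,5400
epileptic09,epileptic09_d01_KCl,KCl,9000
epileptic09,epileptic09_d02_PBS,PBS,-9000
epileptic09,epileptic09_d02_PBS,PBS,-5400
epileptic09,epileptic09_d02_PBS,PBS,-1800
epileptic09,epileptic09_d02_PBS,PBS,1800
epileptic09,epileptic09_d02_PBS,PBS,5400
epileptic09,epileptic09_d02_PBS,PBS,9000
epileptic10,epileptic10_d01_KCl,KCl,5400
epileptic10,epileptic10_d02_PBS,PBS,
epileptic11,epileptic11_d01_KCl,KCl,2700
epileptic11,epileptic11_d01_KCl,KCl,8100
epileptic12,epileptic12_d01_KCl,KCl,5400
epileptic13,epileptic13_d01_KCl,KCl,
epileptic14,epileptic14_d01_KCl,KCl,-5400
epileptic14,epileptic14_d01_KCl,KCl,1800
epileptic14,epileptic14_d01_KCl,KCl,5400
epileptic14,epileptic14_d01_KCl,KCl,9000
epileptic15,epileptic15_d01_KCl,KCl,-5400
epileptic15,epileptic15_d01_KCl,KCl,1800
epileptic15,epileptic15_d01_KCl,KCl,5400
epileptic15,epileptic15_d01_KCl,KCl,9000
epileptic16,epileptic16_d01_KCl,KCl,-5400
epileptic16,epileptic16_d01_KCl,KCl,5400
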