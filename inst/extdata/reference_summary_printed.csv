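# Published Mean and sample-SD rows of the nine-patient index table, as
# printed (one decimal, except the Womersley-number SDs printed with two).
metric,state,mean,sd
mpa_re,pre,825.2,248.6
mpa_re,post,820.7,310.4
mpa_wo,pre,18.5,2.23
mpa_wo,post,18.3,2.49
mpa_vo,pre,116.7,21.6
mpa_vo,post,49.3,20.8
rpa_re,pre,814.0,266.8
rpa_re,post,753.3,533.9
rpa_wo,pre,11.4,1.37
rpa_wo,post,13.1,1.87
rpa_vo,pre,388.9,144.2
rpa_vo,post,136.5,53.4
lpa_re,pre,469.3,129.0
lpa_re,post,489.8,254.0
lpa_wo,pre,12.4,2.31
lpa_wo,post,13.4,3.22
lpa_vo,pre,331.8,120.3
lpa_vo,post,159.6,109.6
ed_mw,pre,93.8,67.7
ed_mw,post,34.0,26.4
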