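feed_id,dm,cp,ee,ndfom,adfom,ash,nfc
alfalfa_hay,924,182,24,318,242,118,358
wheat_straw,894,42,22,794,576,123,19
corn_silage,276,74,38,465,311,79,344
barley_grain,931,89,49,292,113,39,531
corn_grain,884,83,35,129,58,26,727
tmr,578,165,39,328,193,91,377
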