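# Reference metric values for the pairs from make_oracle_pairs(),
# computed once with independent implementations (scikit-image
# structural_similarity with an 11x11 Gaussian window, and the
# canonical scipy-based pixel-domain VIF with sigma_nsq = 2 on the
# 8-bit scale) and frozen here for offline cross-checking.
oracle_reference <- list(
  ssim = c(0.8507494191, 0.8756896213, 0.8133357151, 0.7349478251, 0.6942406233, 0.9774833520, 0.7038079131, 0.8046384535, 0.6996337771, 0.6288942794, 0.7180104238, 0.6128357716, 0.8070257452, 0.7145837246, 0.6553218706, 0.8338367185, 0.8652730076, 0.8133293219, 0.7417396677, 0.6580760258, 0.9759919077, 0.6479254605, 0.8136076886, 0.7226616588, 0.5785142874, 0.6755597273, 0.6098581861, 0.8009238606, 0.7519191145, 0.6324156882, 0.8591491438, 0.8707862403, 0.8142063380, 0.7127833494, 0.6216774017, 0.9765843775, 0.7217164734, 0.7854077523, 0.7097265457, 0.6682645026, 0.7108253795, 0.6369854288, 0.8274433294, 0.6661642289, 0.6335203654, 0.8317020407, 0.8590631434, 0.7885593194, 0.6927378821, 0.6450112523),

  vifp = c(0.4524582548, 0.7218420551, 0.6566534860, 0.4743841201, 0.5305666295, 0.7188395159, 0.4333358128, 0.6624606898, 0.4739662248, 0.5177283002, 0.3257166410, 0.3315120004, 0.6488992287, 0.4817776512, 0.5182432645, 0.4422628543, 0.7197356388, 0.6504781939, 0.4826530514, 0.5171720443, 0.7178922752, 0.3960195105, 0.6512522791, 0.4680790289, 0.5112437579, 0.3174637794, 0.3384413423, 0.6398076598, 0.4792928067, 0.5233779673, 0.4491219234, 0.6381077191, 0.6576094098, 0.4787599509, 0.5048196608, 0.7102575135, 0.4281389934, 0.6512916869, 0.4754705828, 0.5330480721, 0.3103041263, 0.3184696234, 0.6430162330, 0.4702701823, 0.5190541103, 0.4434887812, 0.6588341160, 0.6567428355, 0.4677735066, 0.5242556789)
)
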