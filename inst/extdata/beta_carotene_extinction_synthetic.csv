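"wavelength_nm","extinction_1_per_M_cm"
420,60000
421,61949.9
422,63916.27
423,65897.1
424,67890.4
425,69894.17
426,71906.4
427,73925.1
428,75948.27
429,77973.9
430,80000
431,82024.72
432,84046.83
433,86065.24
434,88078.88
435,90086.66
436,92087.52
437,94080.36
438,96064.1
439,98037.68
440,1e+05
441,101949.22
442,103880.43
443,105787.95
444,107666.09
445,109509.18
446,111311.53
447,113067.47
448,114771.32
449,116417.39
450,118000
451,119515.38
452,120967.35
453,122361.62
454,123703.93
455,125000
456,126246.05
457,127400.3
458,128411.48
459,129228.32
460,129799.53
461,130073.85
462,130000
463,129554.59
464,128825.77
465,127929.6
466,126982.12
467,126099.37
468,125397.41
469,124992.27
470,125000
471,125493.97
472,126376.85
473,127508.6
474,128749.23
475,129958.69
476,130996.99
477,131724.1
478,132000
479,131715.18
480,130882.17
481,129543.98
482,127743.64
483,125524.19
484,122928.63
485,120000
486,116779.46
487,113300.75
488,109595.71
489,105696.21
490,101634.12
491,97441.31
492,93149.62
493,88790.93
494,84397.11
495,80000
496,75628.62
497,71300.54
498,67030.47
499,62833.12
500,58723.21
501,54715.43
502,50824.51
503,47065.16
504,43452.09
505,40000
506,36721.04
507,33617.08
508,30687.4
509,27931.29
510,25348.05
511,22936.96
512,20697.32
513,18628.42
514,16729.55
515,15000
516,13437.2
517,12031.14
518,10769.94
519,9641.72
520,8634.61
521,7736.73
522,6936.21
523,6221.16
524,5579.72
525,5000
526,4471.65
527,3990.36
528,3553.35
529,3157.83
530,2801.01
531,2480.12
532,2192.36
533,1934.94
534,1705.08
535,1500
536,1317.11
537,1154.62
538,1010.97
539,884.57
540,773.83
541,677.2
542,593.07
543,519.89
544,456.05
545,400
546,350.34
547,306.48
548,268
549,234.52
550,205.62
551,180.9
552,159.96
553,142.39
554,127.8
555,115.77
556,105.9
557,97.79
558,91.04
559,85.25
560,80
561,74.97
562,70.08
563,65.34
564,60.76
565,56.33
566,52.06
567,47.95
568,44
569,40.21
570,36.59
571,33.14
572,29.86
573,26.75
574,23.81
575,21.06
576,18.48
577,16.08
578,13.87
579,11.84
580,10
581,8.35
582,6.88
583,5.58
584,4.44
585,3.45
586,2.61
587,1.89
588,1.3
589,0.81
590,0.43
591,0.14
592,0
593,0
594,0
595,0
596,0
597,0
598,0
599,0
600,0
601,0.08
602,0.15
603,0.22
604,0.28
605,0.33
606,0.38
607,0.42
608,0.45
609,0.48
610,0.5
611,0.52
612,0.54
613,0.55
614,0.55
615,0.55
616,0.55
617,0.54
618,0.53
619,0.52
620,0.5
621,0.48
622,0.46
623,0.44
624,0.42
625,0.39
626,0.36
627,0.34
628,0.31
629,0.28
630,0.25
631,0.22
632,0.19
633,0.16
634,0.13
635,0.11
636,0.08
637,0.06
638,0.03
639,0.01
640,0
641,0
642,0
643,0
644,0
645,0
646,0
647,0
648,0
649,0
650,0
651,0.02
652,0.05
653,0.09
654,0.12
655,0.16
656,0.21
657,0.26
658,0.3
659,0.36
660,0.41
661,0.47
662,0.52
663,0.58
664,0.64
665,0.7
666,0.75
667,0.81
668,0.87
669,0.92
670,0.97
671,1.02
672,1.07
673,1.12
674,1.16
675,1.2
676,1.23
677,1.27
678,1.29
679,1.31
680,1.33
681,1.34
682,1.35
683,1.34
684,1.34
685,1.32
686,1.3
687,1.27
688,1.23
689,1.18
690,1.12
691,1.06
692,0.98
693,0.9
694,0.81
695,0.7
696,0.58
697,0.46
698,0.32
699,0.16
700,0
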