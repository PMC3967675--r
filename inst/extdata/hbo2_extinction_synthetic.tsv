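wavelength_nm	extinction_L_per_cm_mol
380	40000
382	45784.2
384	52218
386	59662.4
388	68656.5
390	80000
392	94803
394	113849
396	137645
398	166447
400	2e+05
402	240379
404	289514
406	344652
408	4e+05
410	452876
412	498705
414	524000
416	518739
418	489994
420	450000
422	402121
424	349366
426	3e+05
428	254352
430	213140
432	180000
434	153644
436	131683
438	113919
440	1e+05
442	89208.2
444	80559
446	73427.7
448	67355.8
450	62000
452	57341
454	53387.5
456	49944.1
458	46856.1
460	44000
462	41360.6
464	38969.3
466	36795.7
468	34813.5
470	33000
472	31328.6
474	29789.9
476	28387.8
478	27124.1
480	26000
482	24984.8
484	24060.7
486	23245.3
488	22553.8
490	22000
492	21549.3
494	21180.7
496	20927.4
498	20822.2
500	20900
502	21176.4
504	21633.6
506	22261.9
508	23053.1
510	24000
512	25176.4
514	26628.9
516	28302
518	30123.7
520	32000
522	33949.6
524	36053.5
526	38286.8
528	40616.4
530	43000
532	45487.4
534	47925.3
536	50026
538	52006
540	53319.4
542	53298.2
544	52030.4
546	50085.4
548	48000
550	45925.8
552	43683.9
554	41270
556	38471.3
558	35034.2
560	33000
562	33243.7
564	34878.6
566	37427.5
568	41440.2
570	46010.1
572	49943.5
574	54081.5
576	56405.5
578	54424.7
580	48954.9
582	41769
584	34127.8
586	26423.6
588	19882.6
590	15000
592	11338.5
594	8479.86
596	6358.6
598	4844.37
600	3800
602	3074.57
604	2543.3
606	2145.08
608	1839.69
610	1600
612	1419.2
614	1286.18
616	1180.83
618	1088.9
620	1000
622	914.228
624	836.805
626	767.288
628	705.189
630	650
632	599.878
634	554.101
636	513.535
638	478.724
640	450
642	427.251
644	409.052
646	393.914
648	380.589
650	368
652	356.217
654	345.77
656	336.401
658	327.88
660	320
662	312.67
664	305.957
666	299.912
668	294.578
670	290
672	286.072
674	282.717
676	280.027
678	278.09
680	277
682	276.55
684	276.472
686	276.769
688	277.447
690	278.513
692	279.973
694	281.839
696	284.123
698	286.838
700	290
702	293.736
704	298.128
706	303.122
708	308.665
710	314.701
712	321.171
714	328.01
716	335.147
718	342.505
720	350
722	357.75
724	365.93
726	374.537
728	383.564
730	393.003
732	402.845
734	413.08
736	423.695
738	434.674
740	446
742	457.943
744	470.717
746	484.212
748	498.302
750	512.844
752	527.678
754	542.622
756	557.475
758	572.015
760	586
762	599.463
764	612.618
766	625.483
768	638.083
770	650.446
772	662.605
774	674.597
776	686.463
778	698.247
780	710
782	721.367
784	732.064
786	742.259
788	752.13
790	761.868
792	771.675
794	781.762
796	792.353
798	803.682
800	816
802	829.299
804	843.358
806	858.109
808	873.483
810	889.4
812	905.779
814	922.53
816	939.555
818	956.749
820	974
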