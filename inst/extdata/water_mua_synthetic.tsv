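wavelength_nm	mua_per_mm
380	1.1e-05
382	1.31008e-05
384	1.58111e-05
386	1.92273e-05
388	2.34259e-05
390	2.84334e-05
392	3.4186e-05
394	4.04843e-05
396	4.69542e-05
398	5.30327e-05
400	5.8e-05
402	6.10354e-05
404	6.195e-05
406	6.10952e-05
408	5.89764e-05
410	5.61379e-05
412	5.30812e-05
414	5.02265e-05
416	4.79108e-05
418	4.64132e-05
420	4.6e-05
422	4.64676e-05
424	4.73798e-05
426	4.86852e-05
428	5.03351e-05
430	5.22789e-05
432	5.44595e-05
434	5.68096e-05
436	5.92492e-05
438	6.16829e-05
440	6.4e-05
442	6.62627e-05
444	6.86195e-05
446	7.10786e-05
448	7.36485e-05
450	7.63389e-05
452	7.91603e-05
454	8.21239e-05
456	8.52424e-05
458	8.85294e-05
460	9.2e-05
462	9.56955e-05
464	9.96441e-05
466	0.00010384
468	0.000108275
470	0.000112938
472	0.000117813
474	0.000122883
476	0.000128124
478	0.000133507
480	0.000139
482	0.000144391
484	0.000149569
486	0.000154666
488	0.000159831
490	0.000165241
492	0.000171092
494	0.00017761
496	0.000185055
498	0.00019373
500	0.000204
502	0.000216785
504	0.00023265
506	0.000251442
508	0.000272908
510	0.000296635
512	0.00032199
514	0.000348064
516	0.000373644
518	0.000397211
520	0.000417
522	0.000431734
524	0.000441771
526	0.000447862
528	0.000450945
530	0.000452064
532	0.000452312
534	0.000452797
536	0.000454634
538	0.000458963
540	0.000467
542	0.000478611
544	0.000492612
546	0.000508735
548	0.000526679
550	0.000546105
552	0.000566612
554	0.000587735
556	0.000608934
558	0.000629587
560	0.000649
562	0.000665015
564	0.00067686
566	0.00068602
568	0.000694121
570	0.000702883
572	0.000714119
574	0.000729771
576	0.000752006
578	0.000783366
580	0.000827
582	0.000889221
584	0.000973982
586	0.00108163
588	0.00121212
590	0.00136428
592	0.00153497
594	0.00171825
596	0.00190466
598	0.00208084
600	0.00223
602	0.00234493
604	0.00243165
606	0.00249277
608	0.00253241
610	0.00255576
612	0.00256862
614	0.00257713
616	0.00258756
618	0.00260631
620	0.00264
622	0.00268373
624	0.00272797
626	0.00277272
628	0.00281796
630	0.00286372
632	0.00290997
634	0.00295673
636	0.00300399
638	0.00305174
640	0.0031
642	0.00314879
644	0.00319812
646	0.00324799
648	0.00329837
650	0.00334923
652	0.00340056
654	0.00345233
656	0.00350451
658	0.00355708
660	0.00361
662	0.00365944
664	0.00370312
666	0.00374344
668	0.00378291
670	0.00382418
672	0.00387001
674	0.00392329
676	0.0039871
678	0.00406478
680	0.00416
682	0.00426985
684	0.00438985
686	0.0045218
688	0.00466772
690	0.00482988
692	0.00501089
694	0.0052137
696	0.00544173
698	0.00569895
700	0.00599
702	0.0063271
704	0.00671949
706	0.0071677
708	0.00767175
710	0.00823075
712	0.00884247
714	0.0095029
716	0.0102058
718	0.0109422
720	0.0117
722	0.0125127
724	0.0134201
726	0.0144147
728	0.0154849
730	0.0166139
732	0.0177786
734	0.0189495
736	0.0200898
738	0.0211562
740	0.0221
742	0.0229003
744	0.0235721
746	0.024121
748	0.0245561
750	0.0248896
752	0.0251363
754	0.0253126
756	0.0254362
758	0.0255257
760	0.0256
762	0.025621
764	0.0255475
766	0.0253946
768	0.0251782
770	0.0249139
772	0.0246175
774	0.0243038
776	0.0239874
778	0.0236818
780	0.0234
782	0.0230926
784	0.0227205
786	0.0223113
788	0.0218912
790	0.0214844
792	0.0211136
794	0.0207998
796	0.020563
798	0.020423
800	0.0204
802	0.0205042
804	0.0207201
806	0.0210312
808	0.0214213
810	0.0218739
812	0.0223714
814	0.0228947
816	0.0234229
818	0.0239329
820	0.0244
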