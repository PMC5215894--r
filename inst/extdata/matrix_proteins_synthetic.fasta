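>collagen2 synthetic composition-based surrogate (300 aa)
LGEEDPAYRAFGGAGEESTKQPGEGPPKGTLPRGDLDPPELATAEGGGEGPELGGGQDRA
KHPGNGDRGGNEGPGPARGGGVFGGAIEEPAQDGGGDGSQVPRGGANPVDKIEGAAGVGE
GGTAPPAREAGGGGGAPPFDGSLLGGAGSGEGKPGAARGTVEADDGGGGSKGGPPGGGGE
GAGDGASDQVGEGGGAPKAPERRGGGNGTRGPRSGYQAAGSRPGGGKKGGITLRGDGKDG
QGGSKEGPPGAGGPHGAPNMGGAGGAGPSGEPRAPPGGGRPAGGFSPQPGPGQGPGGMGA
>collagen6 synthetic composition-based surrogate (299 aa)
LLIEIKEGKEVVPQSVNARLFQATVGTESQENSLDGAWFGLNGQGRGDEILLPAPAGGLN
PGHEAFTKYLGPGVPTPVDAVKVRPDITDHGQEEAPENPDKRRDLGLMQRHLETMRSHEG
ASGEGPKNSGGFKASSEADIVFAAIGSCGFAPGCRGMPSLFSNRESTFVIGLGSGSGGRG
VQEHVWEECTGQDRLEDRPGRLDGGKTLAYYKENPPPGYQYRYLACASILVPAGGADPST
QGVFVPDVIKGGEDLLDQSGLTKKATIRQYNVSGENDGKLKHTAGSGRPDNSDPCTVAE
>aggrecan synthetic composition-based surrogate (300 aa)
TYFIQTVTDCGSSTEVVHPVVPLADPPVGTKAESVCTFAGLFTPPDNNQSLLNPRGGRPT
LFIEDRSPAPGACANSSEGKVWEGMDPALVLRVEQPKDLVSWNITSKAHEVGGTPGVGEP
LRTGQTLKLEGLAKTRAGADYLQTTEFIVVPCSGIQSENGAADTFDRTLSLSLGFELDEF
TESGSYFRSKPTAVYKLSISSSPVFPTQSESASAMTNGHKEEGLDSLWAEYSGEHQGQLY
EDCIRSNAQGPTPRPEEMQSFHPTEETEGSELHSIPGGGRTSWDEAPLLPFRDFAEVDQV
>albumin synthetic composition-based surrogate (297 aa)
NYYLEPAKTDRGYHEDETLDECFDTAICATPKTCCTMVELPPEFFKTAHVERELLKEKSC
VRVSNAAKRKDLHKEEEVGKRASHVALFDFVLEAKVKREAEEPLTLAELLYSVNLLKCFC
NLPHEKKCFREYVKVDNQYKKSEKLSAQDLWHIEENRALDTLAVVYHGEALEVLACDLTC
FKALNPKEASFPELSKVCTNGDSCVDIRVCVKCATSTSDKKCADKFFKKFEAVYMCDFHV
VALFRFKQQEGQCDTYKCRDQDLALRLALQLAAAEPFESQTPNIDMLKQEEGQLKPP
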